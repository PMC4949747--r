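# Candidate enumeration, N-acyl specific fragment ions, scheduled SRM
# method construction, isobar analysis and transition-list export.

#' Enumerate candidate NAPE species
#'
#' Builds the cartesian product of a PE-body pool and an N-acyl pool, the
#' in-silico candidate list from which an SRM method is constructed.
#' Duplicate pool entries (and species that coincide at the requested
#' annotation level) are deduplicated; ordering is deterministic (PE
#' carbons, PE double bonds, N-acyl carbons, N-acyl double bonds).
#'
#' @param pe_bodies Character vector of PE bodies, either `"C:D"` totals
#'   (`"36:2"`) for species-level output or `"c1:d1/c2:d2"` molecular
#'   definitions (`"18:1/18:1"`).
#' @param n_acyl_pool Character vector of N-acyl chains, `"n:dn"`.
#' @param level `"species"` or `"molecular"`; molecular requires molecular
#'   PE-body definitions.
#' @return Species tibble (see [parse_nape()]) with one row per distinct
#'   candidate.
#' @examples
#' enumerate_nape(c("36:1", "36:2"), c("16:0", "18:0", "18:1"))
#' @export
enumerate_nape <- function(pe_bodies, n_acyl_pool,
                           level = c("species", "molecular")) {
  level <- match.arg(level)
  if (length(pe_bodies) == 0 || length(n_acyl_pool) == 0) {
    abort("pe_bodies and n_acyl_pool must be non-empty")
  }
  pe_bodies <- unique(normalize_name(pe_bodies))
  n_acyl_pool <- unique(normalize_name(n_acyl_pool))

  has_slash <- stringr::str_detect(pe_bodies, "/")
  if (level == "molecular" && !all(has_slash)) {
    abort("molecular level needs 'c1:d1/c2:d2' PE-body definitions")
  }

  grid <- tidyr::expand_grid(pe = pe_bodies, n = n_acyl_pool)
  names_raw <- ifelse(
    stringr::str_detect(grid$pe, "/") & level == "molecular",
    paste0("PE ", grid$pe, "-N-", grid$n),
    # molecular input at species level: collapse to totals
    purrr::map2_chr(grid$pe, grid$n, function(pe, n) {
      if (stringr::str_detect(pe, "/")) {
        m <- stringr::str_match(pe, "^(\\d+):(\\d+)/(\\d+):(\\d+)$")
        pe <- paste0(
          as.integer(m[2]) + as.integer(m[4]), ":",
          as.integer(m[3]) + as.integer(m[5])
        )
      }
      paste0("PE ", pe, "-N-", n)
    })
  )

  out <- parse_nape(names_raw)
  out <- dplyr::distinct(out, .data$name, .keep_all = TRUE)
  dplyr::arrange(
    out, .data$pe_carbons, .data$pe_db, .data$n_carbons, .data$n_db
  )
}

#' N-acyl specific product ions
#'
#' Collision-induced dissociation of the protonated molecule (or ammonium
#' adduct) cleaves the C-O bonds on either side of the phosphate group,
#' giving two product ions that carry the N-acyl chain and nothing of the
#' O-acyls:
#'
#' * F1 - the protonated N-acyl-phosphoethanolamine, neutral composition
#'   C(n+2) H(2n-2dn+6) N O5 P;
#' * F2 - F1 minus a phosphorus-containing neutral loss: H3PO4 by default
#'   (the dehydrated protonated N-acylethanolamine-type ion) or HPO3 (the
#'   protonated N-acylethanolamine).
#'
#' Both depend only on the N-acyl chain (n, dn), so every PE body with
#' the same N-acyl shares the same product pair -- the basis of N-acyl
#' selective SRM.
#'
#' @param species Species tibble.
#' @param f2_neutral_loss `"H3PO4"` (default) or `"HPO3"`.
#' @return The input with columns `f1_formula`, `f1_mz`, `f2_formula`,
#'   `f2_mz` (product ions as M+H of the stated neutrals).
#' @examples
#' parse_nape("PE 18:1/18:1-N-19:0") |> nape_fragments()
#' @export
nape_fragments <- function(species, f2_neutral_loss = c("H3PO4", "HPO3")) {
  f2_neutral_loss <- match.arg(f2_neutral_loss)
  check_species_tbl(species)
  loss <- if (f2_neutral_loss == "H3PO4") COMP_H3PO4 else COMP_HPO3

  frag <- purrr::map2(species$n_carbons, species$n_db, function(n, dn) {
    f1 <- elemental_composition(
      C = n + 2L, H = 2L * n - 2L * dn + 6L, N = 1L, O = 5L, P = 1L
    )
    f2 <- comp_subtract(f1, loss)
    list(f1 = f1, f2 = f2)
  })
  dplyr::mutate(
    as_tibble(species),
    f1_formula = purrr::map_chr(frag, ~ format_formula(.x$f1)),
    f1_mz = purrr::map_dbl(frag, ~ ion_mz(.x$f1, "M+H")),
    f2_formula = purrr::map_chr(frag, ~ format_formula(.x$f2)),
    f2_mz = purrr::map_dbl(frag, ~ ion_mz(.x$f2, "M+H")),
    f2_neutral_loss = f2_neutral_loss
  )
}

#' Build a scheduled two-transition SRM method
#'
#' Emits two SRM transitions per species -- the quantifier (F1, the
#' phospho-N-acylethanolamine product, the more NAPE-specific fragment)
#' and the qualifier (F2) -- sharing the precursor, adduct and collision
#' energy, each with an acquisition window of `rt_window` minutes centred
#' on the species' expected retention time.
#'
#' @param species Species tibble.
#' @param rt Either a fitted [fit_retention()] model (RTs are predicted)
#'   or a data frame with columns `name` and `rt_min` supplying explicit
#'   retention times.  Species without an RT raise an error naming them.
#' @param adduct Precursor adduct, default `"M+H"`.
#' @param collision_energy Collision energy in eV (default 20, applied to
#'   all species).
#' @param rt_window Acquisition window width, minutes (default 3).
#' @param q1_window,q3_window Quadrupole isolation windows, m/z (default 2).
#' @param cycle_time_s Cycle time used for scheduling statistics (s).
#' @param f2_neutral_loss Neutral loss defining the qualifier, see
#'   [nape_fragments()].
#' @param run_length_min Chromatographic run length, minutes.
#' @return A method tibble of class `nape_method`: one row per transition
#'   with columns `species_name`, `transition_id`, `role`, `precursor_mz`,
#'   `adduct`, `product_mz`, `product_kind`, `collision_energy`,
#'   `polarity`, `rt_center_min`, `rt_start_min`, `rt_end_min`; the
#'   quadrupole windows and cycle time are carried as attributes.
#' @export
build_srm_method <- function(species, rt,
                             adduct = "M+H",
                             collision_energy = 20,
                             rt_window = 3,
                             q1_window = 2, q3_window = 2,
                             cycle_time_s = 0.6,
                             f2_neutral_loss = c("H3PO4", "HPO3"),
                             run_length_min = 18) {
  f2_neutral_loss <- match.arg(f2_neutral_loss)
  if (rt_window <= 0) abort("rt_window must be positive")
  check_species_tbl(species)

  ann <- nape_precursor_mz(species, adduct)
  ann <- nape_fragments(ann, f2_neutral_loss)

  if (inherits(rt, "retention_model")) {
    ann$rt_center_min <- predict_rt(rt, species, run_length = run_length_min)
  } else if (is.data.frame(rt) && all(c("name", "rt_min") %in% names(rt))) {
    idx <- match(ann$name, rt$name)
    if (anyNA(idx)) {
      abort(paste0(
        "no retention time for species: ",
        paste(ann$name[is.na(idx)], collapse = ", ")
      ))
    }
    ann$rt_center_min <- rt$rt_min[idx]
  } else {
    abort("`rt` must be a retention_model or a data frame with name, rt_min")
  }

  long <- tidyr::pivot_longer(
    dplyr::select(
      ann, "name", "precursor_mz", "adduct", "rt_center_min",
      "f1_mz", "f2_mz"
    ),
    cols = c("f1_mz", "f2_mz"),
    names_to = "fragment", values_to = "product_mz"
  )
  out <- dplyr::mutate(
    long,
    species_name = .data$name,
    role = ifelse(.data$fragment == "f1_mz", "quantifier", "qualifier"),
    product_kind = ifelse(.data$fragment == "f1_mz", "phospho_nae", "nae_like"),
    transition_id = paste0(.data$species_name, "|", .data$role),
    collision_energy = collision_energy,
    polarity = "positive",
    rt_start_min = .data$rt_center_min - rt_window / 2,
    rt_end_min = .data$rt_center_min + rt_window / 2
  )
  out <- dplyr::select(
    out, "species_name", "transition_id", "role", "precursor_mz",
    "adduct", "product_mz", "product_kind", "collision_energy",
    "polarity", "rt_center_min", "rt_start_min", "rt_end_min"
  )
  stopifnot(all(out$product_mz < out$precursor_mz))
  new_nape_method(
    out,
    q1_window = q1_window, q3_window = q3_window,
    cycle_time_s = cycle_time_s, f2_neutral_loss = f2_neutral_loss,
    run_length_min = run_length_min
  )
}

new_nape_method <- function(tbl, q1_window, q3_window, cycle_time_s,
                            f2_neutral_loss = "H3PO4", run_length_min = 18) {
  out <- as_tibble(tbl)
  attr(out, "q1_window") <- q1_window
  attr(out, "q3_window") <- q3_window
  attr(out, "cycle_time_s") <- cycle_time_s
  attr(out, "f2_neutral_loss") <- f2_neutral_loss
  attr(out, "run_length_min") <- run_length_min
  class(out) <- c("nape_method", class(out))
  out
}

#' Group species with indistinguishable precursors
#'
#' NAPEs carry three acyl chains, so distinct species frequently share one
#' elemental composition (isobaric structural isomers) and cannot be
#' separated by precursor m/z at any mass resolution.  This partitions a
#' candidate list into precursor-isobar groups and reports, for every pair
#' within a group, whether their N-acyl specific product-ion pairs differ
#' by more than the Q3 tolerance -- i.e. whether two-transition SRM can
#' still tell them apart.
#'
#' @param species Species tibble.
#' @param mz_tolerance Precursor grouping tolerance, m/z (default 0.01);
#'   with tolerance 0 species group exactly when their compositions are
#'   equal.
#' @param q3_tolerance Product-ion match tolerance, m/z (default 1, half
#'   the 2-m/z instrument window).
#' @param adduct Precursor adduct.
#' @return List of class `isobar_report`: `groups` (species tibble with
#'   `precursor_mz` and `isobar_group`) and `pairs` (one row per within-
#'   group pair with logical `resolvable`).
#' @examples
#' parse_nape(c("PE 38:2-N-16:0", "PE 36:2-N-18:0", "PE 36:1-N-18:1")) |>
#'   find_isobars()
#' @export
find_isobars <- function(species, mz_tolerance = 0.01, q3_tolerance = 1,
                         adduct = "M+H") {
  if (mz_tolerance < 0) abort("mz_tolerance must be >= 0")
  ann <- nape_precursor_mz(species, adduct)
  ann <- nape_fragments(ann)
  ann <- dplyr::arrange(ann, .data$precursor_mz, .data$name)

  # greedy sweep: new group whenever the precursor drifts beyond the
  # tolerance from the group minimum
  grp <- integer(nrow(ann))
  g <- 0L
  gmin <- -Inf
  for (i in seq_len(nrow(ann))) {
    if (g == 0L || ann$precursor_mz[i] - gmin > mz_tolerance) {
      g <- g + 1L
      gmin <- ann$precursor_mz[i]
    }
    grp[i] <- g
  }
  ann$isobar_group <- grp

  pairs <- dplyr::group_by(ann, .data$isobar_group)
  pairs <- dplyr::group_modify(pairs, function(d, key) {
    if (nrow(d) < 2) {
      return(tibble(
        species_a = character(), species_b = character(),
        resolvable = logical()
      ))
    }
    idx <- utils::combn(nrow(d), 2)
    tibble(
      species_a = d$name[idx[1, ]],
      species_b = d$name[idx[2, ]],
      resolvable = purrr::map2_lgl(idx[1, ], idx[2, ], function(i, j) {
        prods_a <- c(d$f1_mz[i], d$f2_mz[i])
        prods_b <- c(d$f1_mz[j], d$f2_mz[j])
        # ambiguous if any product of a falls within Q3 tolerance of any of b
        !any(abs(outer(prods_a, prods_b, "-")) <= q3_tolerance)
      })
    )
  })
  pairs <- dplyr::ungroup(pairs)

  structure(
    list(
      groups = dplyr::select(
        ann, "name", "level", "formula", "precursor_mz", "isobar_group"
      ),
      pairs = pairs
    ),
    class = "isobar_report"
  )
}

#' @export
print.isobar_report <- function(x, ...) {
  n_multi <- sum(table(x$groups$isobar_group) > 1)
  cat(
    "Isobar report:", nrow(x$groups), "species in",
    max(x$groups$isobar_group), "precursor groups;",
    n_multi, "group(s) with >1 member\n"
  )
  if (nrow(x$pairs) > 0) {
    amb <- sum(!x$pairs$resolvable)
    cat(
      " ", nrow(x$pairs), "within-group pair(s),",
      amb, "ambiguous after product-ion comparison\n"
    )
  }
  invisible(x)
}

#' Scheduling statistics for an SRM method
#'
#' With scheduled acquisition the instrument only monitors transitions
#' whose retention-time window contains the current time, so the dwell
#' (dynamic scan) time available per transition is the cycle time divided
#' by the number of concurrently scheduled transitions.
#'
#' @param method A `nape_method` table.
#' @param grid_step_min Evaluation grid spacing for the concurrency
#'   profile, minutes.
#' @return List of class `srm_schedule`: `concurrency` (tibble `time_min`,
#'   `n_active`), `transitions` (the method with `concurrency_at_center`
#'   and `dwell_ms`), and `median_dwell_ms`.
#' @export
scheduling_stats <- function(method, grid_step_min = 0.05) {
  cycle <- attr(method, "cycle_time_s") %||% 0.6
  if (cycle <= 0) abort("cycle_time_s must be positive")
  span <- range(c(method$rt_start_min, method$rt_end_min))
  grid <- seq(span[1], span[2], by = grid_step_min)

  n_active_at <- function(t) {
    sum(method$rt_start_min <= t & t <= method$rt_end_min)
  }
  concurrency <- tibble(
    time_min = grid,
    n_active = purrr::map_int(grid, ~ as.integer(n_active_at(.x)))
  )
  conc_center <- purrr::map_int(
    method$rt_center_min, ~ as.integer(n_active_at(.x))
  )
  trans <- dplyr::mutate(
    as_tibble(method),
    concurrency_at_center = conc_center,
    dwell_ms = 1000 * cycle / conc_center
  )
  structure(
    list(
      concurrency = concurrency,
      transitions = trans,
      median_dwell_ms = median(trans$dwell_ms)
    ),
    class = "srm_schedule"
  )
}

#' @export
print.srm_schedule <- function(x, ...) {
  cat(
    "SRM schedule:", nrow(x$transitions), "transitions, peak concurrency",
    max(x$concurrency$n_active), ", median dwell",
    round(x$median_dwell_ms, 1), "ms\n"
  )
  invisible(x)
}

#' Write a transition list to vendor-neutral CSV
#'
#' @param method `nape_method` table.
#' @param path Destination CSV path.
#' @return `path`, invisibly.  m/z values are written with exactly five
#'   decimals; the row order is the method order, so output is stable.
#' @export
write_transition_list <- function(method, path) {
  out <- dplyr::transmute(
    as_tibble(method),
    species_name = .data$species_name,
    precursor_mz = sprintf("%.5f", .data$precursor_mz),
    adduct = .data$adduct,
    product_mz = sprintf("%.5f", .data$product_mz),
    product_kind = .data$product_kind,
    role = .data$role,
    collision_energy = .data$collision_energy,
    polarity = .data$polarity,
    rt_start_min = .data$rt_start_min,
    rt_end_min = .data$rt_end_min
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a transition list written by [write_transition_list()]
#'
#' @param path CSV path.
#' @param q1_window,q3_window,cycle_time_s Method attributes not stored in
#'   the CSV.
#' @return `nape_method` table (m/z at the 5-decimal precision of the file).
#' @export
read_transition_list <- function(path, q1_window = 2, q3_window = 2,
                                 cycle_time_s = 0.6) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(
    "species_name", "precursor_mz", "adduct", "product_mz", "product_kind",
    "role", "collision_energy", "polarity", "rt_start_min", "rt_end_min"
  )
  if (!all(need %in% names(raw))) {
    abort(paste0("transition list missing column(s): ",
                 paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  out <- dplyr::mutate(
    raw,
    precursor_mz = as.numeric(.data$precursor_mz),
    product_mz = as.numeric(.data$product_mz),
    transition_id = paste0(.data$species_name, "|", .data$role),
    rt_center_min = (.data$rt_start_min + .data$rt_end_min) / 2
  )
  out <- dplyr::select(
    out, "species_name", "transition_id", "role", "precursor_mz",
    "adduct", "product_mz", "product_kind", "collision_energy",
    "polarity", "rt_center_min", "rt_start_min", "rt_end_min"
  )
  new_nape_method(
    out, q1_window = q1_window, q3_window = q3_window,
    cycle_time_s = cycle_time_s
  )
}
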