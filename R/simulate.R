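# Synthetic scheduled-SRM chromatogram generator.
#
# Produces the traces a triple quadrupole would record for a NAPE method:
# per transition a Gaussian peak at the species' scheduled retention time,
# with area equal to amount * response_factor (times the ion ratio for the
# qualifier), baseline noise, scheduled acquisition (zero signal outside
# the transition's RT window) and full reproducibility from a seed.  Every
# downstream stage -- peak picking, confirmation, quantification,
# validation -- is tested against this generator's known ground truth.

#' Define a simulated sample
#'
#' The defaults mirror the wet-lab design the assay validates: 100 mg of
#' tissue spiked with 50 pmol of the nonendogenous internal standard
#' PE 18:1/18:1-N-19:0.
#'
#' @param amounts Named numeric vector or data frame (`name`,
#'   `amount_pmol`) of analyte amounts in the extract, pmol.  The internal
#'   standard is added automatically.
#' @param tissue_mass_g Tissue mass, g (default 0.1).
#' @param is_name Internal-standard species (shorthand).
#' @param is_amount_pmol IS spike amount, pmol (default 50).
#' @param response_factors Area units per pmol: single value or named
#'   vector keyed by species name (default 1).
#' @param ion_ratio Qualifier/quantifier area ratio in (0, 1]: single
#'   value or named vector (default 0.35).
#' @param peak_sigma_s Gaussian peak SD, seconds (default 4).
#' @param noise_sd Baseline noise SD, counts (default 0).
#' @param rt_jitter_sd_s Per-species retention-time jitter SD, seconds
#'   (shared by a species' two transitions; default 0).
#' @param sampling_interval_s Acquisition grid spacing, seconds
#'   (default 0.5).
#' @param run_length_min Run length, minutes (default 18).
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `sample_plan`.
#' @export
sample_plan <- function(amounts,
                        tissue_mass_g = 0.1,
                        is_name = "PE 18:1/18:1-N-19:0",
                        is_amount_pmol = 50,
                        response_factors = 1,
                        ion_ratio = 0.35,
                        peak_sigma_s = 4,
                        noise_sd = 0,
                        rt_jitter_sd_s = 0,
                        sampling_interval_s = 0.5,
                        run_length_min = 18,
                        seed = 1L) {
  if (is.data.frame(amounts)) {
    stopifnot(all(c("name", "amount_pmol") %in% names(amounts)))
    amt <- setNames(amounts$amount_pmol, amounts$name)
  } else {
    amt <- amounts
  }
  if (is.null(names(amt)) || any(names(amt) == "")) {
    abort("amounts must be named by species shorthand")
  }
  if (any(amt < 0)) abort("amounts must be >= 0")
  if (tissue_mass_g <= 0) abort("tissue_mass_g must be positive")
  if (peak_sigma_s <= 0) abort("peak_sigma_s must be positive")

  is_name <- format_nape(parse_nape(is_name))
  species <- unique(c(names(amt), is_name))

  lookup <- function(x, default_ok = TRUE) {
    if (length(x) == 1 && is.null(names(x))) {
      setNames(rep(x, length(species)), species)
    } else {
      out <- x[species]
      if (anyNA(out)) {
        abort(paste0(
          "missing per-species value for: ",
          paste(species[is.na(out)], collapse = ", ")
        ))
      }
      setNames(as.numeric(out), species)
    }
  }
  rf <- lookup(response_factors)
  ir <- lookup(ion_ratio)
  if (any(rf <= 0)) abort("response_factors must be positive")
  if (any(ir <= 0 | ir > 1)) abort("ion_ratio must lie in (0, 1]")

  full_amt <- setNames(numeric(length(species)), species)
  full_amt[names(amt)] <- amt
  full_amt[is_name] <- is_amount_pmol

  structure(
    list(
      species = tibble(
        species_name = species,
        amount_pmol = unname(full_amt),
        response_factor = unname(rf),
        ion_ratio = unname(ir)
      ),
      tissue_mass_g = tissue_mass_g,
      is_name = is_name,
      is_amount_pmol = is_amount_pmol,
      peak_sigma_s = peak_sigma_s,
      noise_sd = noise_sd,
      rt_jitter_sd_s = rt_jitter_sd_s,
      sampling_interval_s = sampling_interval_s,
      run_length_min = run_length_min,
      seed = as.integer(seed)
    ),
    class = "sample_plan"
  )
}

#' @export
print.sample_plan <- function(x, ...) {
  cat(
    "Sample plan:", nrow(x$species), "species (IS", x$is_name, ",",
    x$is_amount_pmol, "pmol),", x$tissue_mass_g, "g tissue, noise SD",
    x$noise_sd, ", seed", x$seed, "\n"
  )
  invisible(x)
}

gaussian_trace <- function(times_min, rt_min, area, sigma_s) {
  # area is in intensity*seconds; amplitude = area / (sigma * sqrt(2*pi))
  amp <- area / (sigma_s * sqrt(2 * pi))
  dt_s <- (times_min - rt_min) * 60
  amp * exp(-dt_s^2 / (2 * sigma_s^2))
}

#' Simulate the SRM traces of one sample
#'
#' For each transition of the method, generates a time-intensity trace on
#' a uniform grid over the run: a Gaussian peak centred at the scheduled
#' retention time (plus per-species jitter), with area
#' `amount * response_factor` for the quantifier and additionally times
#' the species ion ratio for the qualifier, plus Gaussian baseline noise;
#' the trace is clipped at zero counts and is zero outside the
#' transition's acquisition window (scheduled SRM records nothing there).
#'
#' @param plan [sample_plan()].
#' @param method `nape_method` from [build_srm_method()]; every plan
#'   species must be present.
#' @return Tibble of class `srm_traces` with columns `transition_id`,
#'   `time_min`, `intensity`, reproducible byte-for-byte from the plan
#'   seed.
#' @export
simulate_sample <- function(plan, method) {
  stopifnot(inherits(plan, "sample_plan"))
  missing <- setdiff(plan$species$species_name, method$species_name)
  if (length(missing) > 0) {
    abort(paste0(
      "plan species missing from method: ", paste(missing, collapse = ", ")
    ))
  }
  times <- seq(0, plan$run_length_min, by = plan$sampling_interval_s / 60)

  withr::with_seed(plan$seed, {
    # one RT jitter per species, shared by its two transitions
    jitter_min <- setNames(
      rnorm(nrow(plan$species), 0, plan$rt_jitter_sd_s) / 60,
      plan$species$species_name
    )
    rows <- purrr::pmap(
      dplyr::filter(
        as_tibble(method),
        .data$species_name %in% plan$species$species_name
      ),
      function(species_name, transition_id, role, rt_center_min,
               rt_start_min, rt_end_min, ...) {
        sp <- plan$species[plan$species$species_name == species_name, ]
        area <- sp$amount_pmol * sp$response_factor *
          if (role == "qualifier") sp$ion_ratio else 1
        rt <- rt_center_min + jitter_min[[species_name]]
        signal <- gaussian_trace(times, rt, area, plan$peak_sigma_s)
        if (plan$noise_sd > 0) {
          signal <- signal + rnorm(length(times), 0, plan$noise_sd)
        }
        in_window <- times >= rt_start_min & times <= rt_end_min
        intensity <- ifelse(in_window, pmax(signal, 0), 0)
        tibble(
          transition_id = transition_id,
          time_min = times,
          intensity = intensity
        )
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("srm_traces", class(out))
  out
}

# deterministic per-(level, replicate) seed derivation; kept below 2^31
derive_seed <- function(base_seed, level_index, replicate_index) {
  as.integer(
    (as.numeric(base_seed) + 1000003 * level_index +
       10007 * replicate_index) %% .Machine$integer.max
  )
}

#' Simulate a spiked calibration series
#'
#' Emulates the validation design: tissue aliquots spiked with
#' nonendogenous analytes at a ladder of concentration levels, each level
#' fully processed in replicate, with a constant internal-standard spike.
#' Two multiplicative lognormal error components emulate preparation
#' variability: a per-sample yield factor shared by every species
#' including the IS (so it cancels under IS normalisation -- the reason
#' the assay needs an internal standard) and a per-species residual
#' factor, shared by the species' two transitions, that survives
#' normalisation and limits linearity.
#'
#' @param levels_pmol_per_g Spike levels, pmol per g tissue
#'   (default: nine levels spanning 10-2300 pmol/g).
#' @param replicates Replicates per level (default 3).
#' @param spike_names Species spiked at each level (shorthand names).
#' @param template [sample_plan()] carrying everything else (IS, response
#'   factors, noise, tissue mass); its `amounts` entries are the
#'   endogenous background (may be empty).
#' @param method `nape_method`.
#' @param cv Residual per-species lognormal CV after IS normalisation
#'   (default 0.05).
#' @param prep_cv Per-sample preparation-yield lognormal CV, shared by all
#'   species incl. IS (default 0.27).
#' @return Nested tibble of class `nape_calibration`: one row per
#'   level x replicate with `level_pmol_per_g`, `replicate`, `seed`,
#'   `truth` (list of per-species amount tibbles) and `traces` (list of
#'   `srm_traces`).
#' @export
simulate_calibration <- function(levels_pmol_per_g = c(10, 20, 50, 100, 200,
                                                       500, 1000, 1600, 2300),
                                 replicates = 3,
                                 spike_names,
                                 template,
                                 method,
                                 cv = 0.05,
                                 prep_cv = 0.27) {
  stopifnot(inherits(template, "sample_plan"))
  if (any(levels_pmol_per_g <= 0)) abort("levels must be positive")
  if (replicates < 1) abort("replicates must be >= 1")
  spike_names <- format_nape(parse_nape(spike_names))

  sdlog_of_cv <- function(cv) sqrt(log(1 + cv^2))

  grid <- tidyr::expand_grid(
    level_index = seq_along(levels_pmol_per_g),
    replicate = seq_len(replicates)
  )
  rows <- purrr::pmap(grid, function(level_index, replicate) {
    level <- levels_pmol_per_g[level_index]
    seed <- derive_seed(template$seed, level_index, replicate)

    base_amt <- setNames(
      template$species$amount_pmol, template$species$species_name
    )
    amt <- base_amt
    spike_amt <- level * template$tissue_mass_g
    for (nm in spike_names) {
      amt[nm] <- if (nm %in% names(amt)) amt[[nm]] + spike_amt else spike_amt
    }
    amt <- amt[setdiff(names(amt), template$is_name)]

    rf <- setNames(
      template$species$response_factor, template$species$species_name
    )
    all_names <- union(names(amt), template$is_name)
    rf_full <- rf[all_names]
    rf_full[is.na(rf_full)] <- 1

    # preparation-error factors drawn from a derived, documented seed
    pert <- withr::with_seed(seed + 1L, {
      yield <- if (prep_cv > 0) {
        exp(rnorm(1, -sdlog_of_cv(prep_cv)^2 / 2, sdlog_of_cv(prep_cv)))
      } else 1
      resid <- if (cv > 0) {
        exp(rnorm(
          length(all_names), -sdlog_of_cv(cv)^2 / 2, sdlog_of_cv(cv)
        ))
      } else rep(1, length(all_names))
      resid <- setNames(resid, all_names)
      # cv is defined as the residual CV of the IS-normalised response:
      # the IS itself carries only the shared preparation-yield factor
      resid[template$is_name] <- 1
      list(yield = yield, resid = resid)
    })
    rf_eff <- rf_full * pert$yield * pert$resid

    plan <- sample_plan(
      amounts = amt,
      tissue_mass_g = template$tissue_mass_g,
      is_name = template$is_name,
      is_amount_pmol = template$is_amount_pmol,
      response_factors = rf_eff,
      ion_ratio = setNames(
        template$species$ion_ratio, template$species$species_name
      )[all_names] |> (\(x) {x[is.na(x)] <- 0.35; x})(),
      peak_sigma_s = template$peak_sigma_s,
      noise_sd = template$noise_sd,
      rt_jitter_sd_s = template$rt_jitter_sd_s,
      sampling_interval_s = template$sampling_interval_s,
      run_length_min = template$run_length_min,
      seed = seed
    )
    truth <- tibble(
      species_name = names(amt),
      amount_pmol = unname(amt),
      conc_pmol_per_g = unname(amt) / template$tissue_mass_g,
      spiked = names(amt) %in% spike_names
    )
    tibble(
      level_pmol_per_g = level,
      replicate = replicate,
      seed = seed,
      truth = list(truth),
      traces = list(simulate_sample(plan, method))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nape_calibration", class(out))
  out
}

#' Inject a co-eluting isobaric interference
#'
#' Adds a second Gaussian peak to a single transition -- the signature of
#' an isobaric interferer that shares the precursor and one product ion
#' but not both.  Used to demonstrate that two-transition confirmation
#' (ion-ratio check) catches what a single transition cannot.
#'
#' @param traces `srm_traces`.
#' @param method `nape_method` (provides the target's scheduled RT and
#'   window).
#' @param transition_id Transition to contaminate.
#' @param rt_offset_min Interferer apex offset from the target's scheduled
#'   RT, minutes.
#' @param area Interferer peak area, intensity-seconds (0 leaves traces
#'   unchanged).
#' @param peak_sigma_s Interferer peak SD, seconds.
#' @return Modified `srm_traces`; the interference is masked by the
#'   transition's acquisition window like any real signal.
#' @export
inject_interference <- function(traces, method, transition_id,
                                rt_offset_min, area, peak_sigma_s = 4) {
  row <- dplyr::filter(as_tibble(method), .data$transition_id == !!transition_id)
  if (nrow(row) != 1) {
    abort(paste0("unknown transition '", transition_id, "'"))
  }
  if (area == 0) return(traces)
  sel <- traces$transition_id == transition_id
  if (!any(sel)) abort(paste0("no trace for transition '", transition_id, "'"))
  t <- traces$time_min[sel]
  extra <- gaussian_trace(
    t, row$rt_center_min + rt_offset_min, area, peak_sigma_s
  )
  in_window <- t >= row$rt_start_min & t <= row$rt_end_min
  traces$intensity[sel] <- pmax(
    traces$intensity[sel] + ifelse(in_window, extra, 0), 0
  )
  traces
}

#' Plot SRM traces
#'
#' @param object `srm_traces`.
#' @param ... Unused.
#' @return ggplot: one facet per transition.
#' @export
#' @method autoplot srm_traces
autoplot.srm_traces <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$intensity > 0 | TRUE)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~transition_id, scales = "free_y") +
    ggplot2::labs(
      x = "time (min)", y = "intensity (counts)",
      title = "SRM chromatograms"
    )
}
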