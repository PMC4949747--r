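# Neutral text formats: species lists, chromatogram traces, results
# tables and the YAML run configuration.

#' Read a species list CSV
#'
#' Accepts either a single `name` column of shorthand names or the
#' three-column form `pe`, `n_acyl`, `level` (`"36:1"`, `"16:0"`,
#' `"species"`).
#'
#' @param path CSV path.
#' @return Species tibble (see [parse_nape()]).
#' @export
read_species_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if ("name" %in% names(d)) {
    parse_nape(d$name)
  } else if (all(c("pe", "n_acyl", "level") %in% names(d))) {
    parse_nape(paste0("PE ", d$pe, "-N-", d$n_acyl))
  } else {
    abort("species CSV needs a 'name' column or columns pe, n_acyl, level")
  }
}

#' Write a species list CSV
#'
#' @param species Species tibble.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(species, path) {
  check_species_tbl(species)
  readr::write_csv(tibble(name = format_nape(species)), path)
  invisible(path)
}

#' Read/write long-format SRM traces
#'
#' Traces travel as long CSV with columns `transition_id`, `time_min`,
#' `intensity`.
#'
#' @param traces `srm_traces` tibble.
#' @param path CSV path.
#' @return `write_traces_csv()`: `path` invisibly; `read_traces_csv()`:
#'   `srm_traces` tibble.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(all(c("transition_id", "time_min", "intensity") %in% names(traces)))
  readr::write_csv(traces[, c("transition_id", "time_min", "intensity")], path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("transition_id", "time_min", "intensity")
  if (!all(need %in% names(d))) {
    abort(paste0("traces CSV missing column(s): ",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  }
  out <- as_tibble(d[, need])
  class(out) <- c("srm_traces", class(out))
  out
}

#' Write per-species results as TSV
#'
#' @param results `nape_results` from [quantify_sample()].
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(as_tibble(results), path)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

CONFIG_DEFAULTS <- list(
  adduct = "M+H",
  collision_energy = 20,
  rt_window_min = 3,
  q1_window = 2,
  q3_window = 2,
  cycle_time_s = 0.6,
  f2_neutral_loss = "H3PO4",
  is_name = "PE 18:1/18:1-N-19:0",
  is_amount_pmol = 50,
  tissue_mass_g = 0.1,
  rt_delta_min = 0.05,
  ratio_rel_tol = 0.30,
  snr_threshold = 10,
  run_length_min = 18,
  simulator = list(
    peak_sigma_s = 4,
    noise_sd = 0,
    rt_jitter_sd_s = 0,
    sampling_interval_s = 0.5,
    ion_ratio = 0.35,
    cv = 0.05,
    prep_cv = 0.27,
    seed = 1
  )
)

POSITIVE_KEYS <- c(
  "collision_energy", "rt_window_min", "q1_window", "q3_window",
  "cycle_time_s", "is_amount_pmol", "tissue_mass_g", "rt_delta_min",
  "ratio_rel_tol", "snr_threshold", "run_length_min"
)

#' Build a validated run configuration
#'
#' All defaults are the assay's documented operating point (M+H precursor,
#' 20 eV, 3-min scheduled windows, 2-m/z quadrupole windows, 50 pmol IS in
#' 0.1 g tissue).  Unknown keys are rejected by name so typos cannot
#' silently fall back to defaults.
#'
#' @param ... Overrides for top-level keys; `simulator` may be a list of
#'   simulator-block overrides.
#' @return List of class `nape_config`.
#' @export
nape_config <- function(...) {
  override <- list(...)
  build_config(override)
}

build_config <- function(override) {
  unknown <- setdiff(names(override), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(override$simulator)) {
    unk_sim <- setdiff(
      names(override$simulator), names(CONFIG_DEFAULTS$simulator)
    )
    if (length(unk_sim) > 0) {
      abort(paste0(
        "unknown simulator config key(s): ", paste(unk_sim, collapse = ", ")
      ))
    }
  }
  cfg <- modifyList(CONFIG_DEFAULTS, override)
  for (k in POSITIVE_KEYS) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      abort(paste0("config key '", k, "' must be a positive number"))
    }
  }
  adduct_info(cfg$adduct) # validates
  if (!cfg$f2_neutral_loss %in% c("H3PO4", "HPO3")) {
    abort("f2_neutral_loss must be 'H3PO4' or 'HPO3'")
  }
  cfg$is_name <- format_nape(parse_nape(cfg$is_name))
  structure(cfg, class = "nape_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [nape_config()].
#' @return `nape_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}
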