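# Two-transition confirmation and internal-standard quantification.

#' Confirm a species from its quantifier/qualifier peaks
#'
#' A species is considered detected only when (i) both transitions show a
#' peak, (ii) the two apexes co-elute within `rt_delta`, and (iii) the
#' observed ion ratio (qualifier area / quantifier area) lies within
#' `ratio_rel_tol` of the expected ratio.  Every failed criterion is named
#' in `flags`; the two-transition design exists precisely so that an
#' isobaric interference on one product ion shows up as an ion-ratio
#' failure instead of a silently wrong concentration.
#'
#' @param quant_peaks,qual_peaks Peak tables from [detect_peaks()] for the
#'   quantifier and qualifier transitions (largest-area peak is used).
#' @param expected_ratio Expected qualifier/quantifier area ratio (> 0).
#' @param rt_delta Maximum apex RT difference, minutes (default 0.05).
#' @param ratio_rel_tol Relative ion-ratio tolerance (default 0.30).
#' @return List: `detected` (logical), `flags` (character vector, empty
#'   when detected), `rt_apex_min`, `quantifier_area`, `qualifier_area`,
#'   `ion_ratio`, `snr` (quantifier).
#' @export
confirm_species <- function(quant_peaks, qual_peaks, expected_ratio,
                            rt_delta = 0.05, ratio_rel_tol = 0.30) {
  if (expected_ratio <= 0) abort("expected_ratio must be positive")
  flags <- character()
  qp <- if (nrow(quant_peaks) > 0) quant_peaks[1, ] else NULL
  lp <- if (nrow(qual_peaks) > 0) qual_peaks[1, ] else NULL
  if (is.null(qp)) flags <- c(flags, "missing_quantifier")
  if (is.null(lp)) flags <- c(flags, "missing_qualifier")

  ion_ratio <- NA_real_
  if (!is.null(qp) && !is.null(lp)) {
    if (abs(qp$rt_apex_min - lp$rt_apex_min) > rt_delta) {
      flags <- c(flags, "rt_mismatch")
    }
    ion_ratio <- lp$area / qp$area
    if (abs(ion_ratio - expected_ratio) > ratio_rel_tol * expected_ratio) {
      flags <- c(flags, "ion_ratio_fail")
    }
  }
  list(
    detected = length(flags) == 0,
    flags = flags,
    rt_apex_min = if (!is.null(qp)) qp$rt_apex_min else NA_real_,
    quantifier_area = if (!is.null(qp)) qp$area else NA_real_,
    qualifier_area = if (!is.null(lp)) lp$area else NA_real_,
    ion_ratio = ion_ratio,
    snr = if (!is.null(qp)) qp$snr else NA_real_
  )
}

#' Quantify all species of a method in one sample
#'
#' Internal-standard one-point calibration: for every confirmed species,
#'
#'   concentration = (quantifier area / IS quantifier area)
#'                   * is_amount / tissue_mass          (pmol per g)
#'
#' The qualifier is used for confirmation only.  The internal standard
#' must itself be detected; a sample without a detectable IS is invalid
#' and raises an error.
#'
#' @param traces `srm_traces` (long tibble `transition_id`, `time_min`,
#'   `intensity`).
#' @param method `nape_method`.
#' @param is_name Internal-standard species name (canonical shorthand).
#' @param is_amount_pmol IS spike amount, pmol (default 50).
#' @param tissue_mass_g Tissue mass, g (default 0.1).
#' @param expected_ratios Expected qualifier/quantifier ion ratios: single
#'   value (default 0.35) or named vector keyed by species name.
#' @param rt_delta,ratio_rel_tol Confirmation tolerances, see
#'   [confirm_species()].
#' @param snr_threshold Quantifier S/N below which a detected species is
#'   flagged `below_loq` (default 10).
#' @return Tibble of class `nape_results`: one row per method species with
#'   `species_name`, `detected`, `rt_apex_min`, `quantifier_area`,
#'   `qualifier_area`, `ion_ratio`, `snr`, `conc_pmol_per_g` (`NA` unless
#'   detected) and `flags` (comma-joined, `""` when clean).
#' @export
quantify_sample <- function(traces, method,
                            is_name = "PE 18:1/18:1-N-19:0",
                            is_amount_pmol = 50,
                            tissue_mass_g = 0.1,
                            expected_ratios = 0.35,
                            rt_delta = 0.05,
                            ratio_rel_tol = 0.30,
                            snr_threshold = 10) {
  if (tissue_mass_g <= 0) abort("tissue_mass_g must be positive")
  is_name <- format_nape(parse_nape(is_name))
  m <- as_tibble(method)
  species <- unique(m$species_name)
  if (!is_name %in% species) {
    abort(paste0("internal standard '", is_name, "' is not in the method"))
  }

  ratio_for <- function(name) {
    if (length(expected_ratios) == 1 && is.null(names(expected_ratios))) {
      expected_ratios
    } else {
      if (!name %in% names(expected_ratios)) {
        abort(paste0("no expected ion ratio for ", name))
      }
      expected_ratios[[name]]
    }
  }

  one <- function(name) {
    rows <- m[m$species_name == name, ]
    quant <- rows[rows$role == "quantifier", ]
    qual <- rows[rows$role == "qualifier", ]
    window <- c(quant$rt_start_min, quant$rt_end_min)
    tq <- dplyr::filter(traces, .data$transition_id == quant$transition_id)
    tl <- dplyr::filter(traces, .data$transition_id == qual$transition_id)
    quant_peaks <- if (nrow(tq) > 0) detect_peaks(tq, window) else
      detect_peaks(tibble(time_min = numeric(), intensity = numeric()))
    qual_peaks <- if (nrow(tl) > 0) {
      detect_peaks(tl, c(qual$rt_start_min, qual$rt_end_min))
    } else {
      quant_peaks[0, ]
    }
    conf <- confirm_species(
      quant_peaks, qual_peaks, ratio_for(name),
      rt_delta = rt_delta, ratio_rel_tol = ratio_rel_tol
    )
    tibble(
      species_name = name,
      detected = conf$detected,
      rt_apex_min = conf$rt_apex_min,
      quantifier_area = conf$quantifier_area,
      qualifier_area = conf$qualifier_area,
      ion_ratio = conf$ion_ratio,
      snr = conf$snr,
      flags = paste(conf$flags, collapse = ",")
    )
  }
  out <- purrr::map(species, one)
  out <- dplyr::bind_rows(out)

  is_row <- out[out$species_name == is_name, ]
  if (!is_row$detected) {
    abort(paste0(
      "internal standard not detected (flags: ", is_row$flags,
      "); sample is invalid"
    ))
  }
  is_area <- is_row$quantifier_area

  out <- dplyr::mutate(
    out,
    conc_pmol_per_g = ifelse(
      .data$detected,
      .data$quantifier_area / is_area * is_amount_pmol / tissue_mass_g,
      NA_real_
    ),
    flags = ifelse(
      .data$detected & .data$snr < snr_threshold,
      sub("^,", "", paste(.data$flags, "below_loq", sep = ",")),
      .data$flags
    )
  )
  class(out) <- c("nape_results", class(out))
  out
}
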