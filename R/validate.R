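# Assay validation statistics: unweighted linearity, back-calculated
# accuracy, replicate precision (RSD) and the lower limit of
# quantification, plus a report object that runs the lot on a simulated
# calibration series.

#' Fit an unweighted calibration line
#'
#' Ordinary least squares of the response ratio (analyte quantifier area /
#' IS quantifier area) on the nominal spiked concentration.  Unweighted by
#' design: the assay's validation style fits all levels with equal weight.
#'
#' @param data Data frame of calibration points.
#' @param level,response Columns holding the nominal concentration
#'   (pmol/g) and the response ratio (tidy-eval; defaults
#'   `level_pmol_per_g`, `response_ratio`).
#' @return Object of class `linearity_fit` with `slope`, `intercept`,
#'   `r2`, `n_points`; supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_linearity <- function(data, level = level_pmol_per_g,
                          response = response_ratio) {
  d <- tibble(
    level = dplyr::pull(data, {{ level }}),
    response = dplyr::pull(data, {{ response }})
  )
  d <- d[stats::complete.cases(d), ]
  if (length(unique(d$level)) < 3) {
    abort("need at least 3 distinct concentration levels")
  }
  fit <- lm(response ~ level, data = d)
  cf <- coef(fit)
  tss <- sum((d$response - mean(d$response))^2)
  # suppressWarnings: summary.lm warns on (desirable) exact fits
  r2 <- if (tss == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      slope = unname(cf[["level"]]),
      intercept = unname(cf[["(Intercept)"]]),
      r2 = r2,
      n_points = nrow(d),
      fit = fit,
      data = d
    ),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(
    "Calibration line (unweighted):",
    "slope", signif(x$slope, 6),
    ", intercept", signif(x$intercept, 6),
    ", R^2", round(x$r2, 4),
    ", n =", x$n_points, "\n"
  )
  invisible(x)
}

#' @export
#' @method tidy linearity_fit
tidy.linearity_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
#' @method glance linearity_fit
glance.linearity_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r2, nobs = x$n_points
  )
}

#' @export
#' @method autoplot linearity_fit
autoplot.linearity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$level, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, linetype = 2
    ) +
    ggplot2::labs(
      x = "nominal concentration (pmol/g)",
      y = "response ratio (area / IS area)",
      title = sprintf(
        "Unweighted calibration: slope %.4f, R² %.4f",
        object$slope, object$r2
      )
    )
}

#' Back-calculated accuracy at QC levels
#'
#' Back-calculates QC concentrations through the calibration line,
#' `(response - intercept) / slope`, averages replicates per level, and
#' reports the percent deviation from nominal (absolute value, with the
#' signed bias alongside).
#'
#' @param fit `linearity_fit`.
#' @param qc_points Data frame of QC measurements.
#' @param level,response Tidy-eval columns as in [fit_linearity()].
#' @return Tibble per level: `level_pmol_per_g`, `back_calculated`,
#'   `accuracy_pct` (absolute deviation), `bias_pct` (signed),
#'   `n_replicates`, `flag` (`"negative_back_calc"` when applicable).
#' @export
qc_accuracy <- function(fit, qc_points, level = level_pmol_per_g,
                        response = response_ratio) {
  stopifnot(inherits(fit, "linearity_fit"))
  if (fit$slope == 0) abort("calibration slope is zero; cannot back-calculate")
  d <- tibble(
    level = dplyr::pull(qc_points, {{ level }}),
    response = dplyr::pull(qc_points, {{ response }})
  )
  if (any(d$level <= 0)) abort("QC levels must be positive")
  d$back <- (d$response - fit$intercept) / fit$slope
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$level),
    back_calculated = mean(.data$back),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  neg <- out$back_calculated < 0
  if (any(neg)) {
    warn("negative back-calculated concentration at one or more QC levels")
  }
  dplyr::transmute(
    out,
    level_pmol_per_g = .data$level,
    back_calculated = .data$back_calculated,
    accuracy_pct = 100 * abs(.data$back_calculated - .data$level) / .data$level,
    bias_pct = 100 * (.data$back_calculated - .data$level) / .data$level,
    n_replicates = .data$n_replicates,
    flag = ifelse(neg, "negative_back_calc", "")
  )
}

#' Relative standard deviation of replicate concentrations
#'
#' @param x Numeric vector of replicate concentrations (>= 2 values).
#' @return RSD in percent, `100 * sd / mean`; `NA` with a warning when the
#'   mean is zero.
#' @export
precision_rsd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("need at least 2 replicates for precision")
  m <- mean(x)
  if (m == 0) {
    warn("mean concentration is zero; RSD undefined")
    return(NA_real_)
  }
  100 * sd(x) / m
}

#' Lower limit of quantification from a calibration series
#'
#' The lowest calibration level at which every replicate is detected with
#' quantifier S/N at or above the threshold (10:1 by convention).
#'
#' @param per_sample Tibble with one row per level x replicate per
#'   analyte: columns `level_pmol_per_g`, `detected`, `snr`.
#' @param snr_threshold S/N threshold (default 10).
#' @return List of class `lloq_estimate`: `lloq_pmol_per_g` (`NA` when no
#'   level qualifies, with `note = "above highest tested level"`) and
#'   `per_level` (level, n, all detected, min snr, qualifies).
#' @export
lloq_estimate <- function(per_sample, snr_threshold = 10) {
  if (length(unique(per_sample$level_pmol_per_g)) < 2) {
    abort("calibration must span at least 2 levels")
  }
  per_level <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$level_pmol_per_g),
    n = dplyr::n(),
    all_detected = all(.data$detected),
    min_snr = suppressWarnings(min(.data$snr, na.rm = TRUE)),
    .groups = "drop"
  )
  per_level <- dplyr::arrange(per_level, .data$level_pmol_per_g)
  per_level$qualifies <- per_level$all_detected &
    is.finite(per_level$min_snr) & per_level$min_snr >= snr_threshold
  ok <- which(per_level$qualifies)
  structure(
    list(
      lloq_pmol_per_g = if (length(ok) > 0) {
        per_level$level_pmol_per_g[min(ok)]
      } else NA_real_,
      note = if (length(ok) > 0) "" else "above highest tested level",
      per_level = per_level,
      snr_threshold = snr_threshold
    ),
    class = "lloq_estimate"
  )
}

#' @export
print.lloq_estimate <- function(x, ...) {
  if (is.na(x$lloq_pmol_per_g)) {
    cat("LLOQ: above highest tested level (S/N threshold",
        x$snr_threshold, ")\n")
  } else {
    cat("LLOQ:", x$lloq_pmol_per_g, "pmol/g (S/N threshold",
        x$snr_threshold, ")\n")
  }
  invisible(x)
}

#' Run the full validation battery on a simulated calibration
#'
#' Quantifies every sample of a calibration series, then derives per-
#' analyte unweighted linearity, QC accuracy (when QC levels are given),
#' replicate precision at the highest level, and the LLOQ.
#'
#' @param calibration `nape_calibration` from [simulate_calibration()].
#' @param method `nape_method`.
#' @param analytes Character vector of analyte names to validate
#'   (default: all spiked species found in the ground truth).
#' @param qc_levels Levels (pmol/g) treated as QC points for accuracy and
#'   excluded from the calibration fit, mirroring a low/medium/high QC
#'   design; `NULL` fits all levels and skips accuracy.
#' @param is_name,is_amount_pmol,tissue_mass_g,expected_ratios,snr_threshold
#'   Passed to [quantify_sample()].
#' @return Object of class `validation_report`: tibbles `linearity`
#'   (Analyte/Slope/Intercept/R2 style), `accuracy`, `precision`, `lloq`,
#'   plus `per_sample` (all quantified calibration rows).
#' @export
validate_calibration <- function(calibration, method,
                                 analytes = NULL,
                                 qc_levels = NULL,
                                 is_name = "PE 18:1/18:1-N-19:0",
                                 is_amount_pmol = 50,
                                 tissue_mass_g = 0.1,
                                 expected_ratios = 0.35,
                                 snr_threshold = 10) {
  stopifnot(inherits(calibration, "nape_calibration"))
  is_name <- format_nape(parse_nape(is_name))

  per_sample <- purrr::pmap(
    calibration[, c("level_pmol_per_g", "replicate", "truth", "traces")],
    function(level_pmol_per_g, replicate, truth, traces) {
      res <- quantify_sample(
        traces, method,
        is_name = is_name, is_amount_pmol = is_amount_pmol,
        tissue_mass_g = tissue_mass_g, expected_ratios = expected_ratios,
        snr_threshold = snr_threshold
      )
      is_area <- res$quantifier_area[res$species_name == is_name]
      dplyr::mutate(
        as_tibble(res),
        level_pmol_per_g = level_pmol_per_g,
        replicate = replicate,
        response_ratio = .data$quantifier_area / is_area
      )
    }
  )
  per_sample <- dplyr::bind_rows(per_sample)

  if (is.null(analytes)) {
    truth1 <- calibration$truth[[1]]
    analytes <- truth1$species_name[truth1$spiked]
  }

  cal_rows <- dplyr::filter(per_sample, .data$species_name %in% analytes)
  fit_rows <- if (is.null(qc_levels)) cal_rows else {
    dplyr::filter(cal_rows, !.data$level_pmol_per_g %in% qc_levels)
  }

  fits <- purrr::map(
    setNames(analytes, analytes),
    function(a) {
      fit_linearity(dplyr::filter(fit_rows, .data$species_name == a))
    }
  )
  linearity <- purrr::imap(fits, function(f, a) {
    tibble(
      analyte = a, slope = f$slope, intercept = f$intercept,
      r2 = f$r2, n_points = f$n_points
    )
  })
  linearity <- dplyr::bind_rows(linearity)

  accuracy <- NULL
  if (!is.null(qc_levels)) {
    accuracy <- purrr::imap(fits, function(f, a) {
      qc <- dplyr::filter(
        cal_rows, .data$species_name == a,
        .data$level_pmol_per_g %in% qc_levels
      )
      if (nrow(qc) == 0) return(NULL)
      dplyr::mutate(qc_accuracy(f, qc), analyte = a, .before = 1)
    })
    accuracy <- dplyr::bind_rows(accuracy)
  }

  top_level <- max(cal_rows$level_pmol_per_g)
  precision <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(cal_rows, .data$level_pmol_per_g == top_level),
      .data$species_name
    ),
    level_pmol_per_g = top_level,
    rsd_pct = precision_rsd(.data$conc_pmol_per_g),
    n = dplyr::n(),
    .groups = "drop"
  )

  lloq <- purrr::imap(fits, function(f, a) {
    per <- dplyr::filter(cal_rows, .data$species_name == a)
    est <- lloq_estimate(per, snr_threshold = snr_threshold)
    tibble(
      analyte = a,
      lloq_pmol_per_g = est$lloq_pmol_per_g,
      note = est$note
    )
  })
  lloq <- dplyr::bind_rows(lloq)

  structure(
    list(
      linearity = linearity,
      accuracy = accuracy,
      precision = precision,
      lloq = lloq,
      per_sample = per_sample,
      snr_threshold = snr_threshold
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Assay validation report\n\nLinearity (unweighted):\n")
  tab <- dplyr::transmute(
    x$linearity,
    Analyte = .data$analyte,
    Slope = sprintf("%.4f", .data$slope),
    Intercept = sprintf("%.4f", .data$intercept),
    `R^2` = sprintf("%.4f", .data$r2)
  )
  print.data.frame(as.data.frame(tab), row.names = FALSE)
  if (!is.null(x$accuracy) && nrow(x$accuracy) > 0) {
    cat("\nAccuracy (back-calculated, % deviation from nominal):\n")
    acc <- dplyr::summarise(
      dplyr::group_by(x$accuracy, .data$level_pmol_per_g),
      mean_accuracy_pct = mean(.data$accuracy_pct),
      .groups = "drop"
    )
    print.data.frame(as.data.frame(acc), row.names = FALSE)
  }
  if (nrow(x$lloq) > 0) {
    cat("\nLLOQ (S/N >=", x$snr_threshold, "):\n")
    print.data.frame(as.data.frame(x$lloq), row.names = FALSE)
  }
  invisible(x)
}

#' Write a validation report to JSON (plus readable text table)
#'
#' @param report `validation_report`.
#' @param json_path Output JSON path.
#' @param txt_path Optional path for the human-readable table (the print
#'   output).
#' @return `json_path`, invisibly.
#' @export
write_validation_report <- function(report, json_path, txt_path = NULL) {
  payload <- list(
    linearity = report$linearity,
    accuracy = report$accuracy,
    precision = report$precision,
    lloq = report$lloq
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(txt_path)) {
    txt <- utils::capture.output(print(report))
    writeLines(txt, txt_path)
  }
  invisible(json_path)
}
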