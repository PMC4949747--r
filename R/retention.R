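# Equivalent-carbon-number retention model.
#
# On reversed-phase columns lipid retention grows with the total number of
# acyl carbons and shrinks with the number of double bonds.  The model here
# is the bivariate linear generalisation of the classical ECN predictor:
#
#   rt = intercept + carbon_coeff * (C + n) + db_coeff * (D + dn)
#
# where C:D are the PE-body totals and n:dn the N-acyl chain.  The single-
# parameter ECN form (retention a function of C - k*DB) is the special case
# db_coeff = -k * carbon_coeff.

total_chain_counts <- function(species) {
  check_species_tbl(species)
  list(
    total_c = species$pe_carbons + species$n_carbons,
    total_db = species$pe_db + species$n_db
  )
}

#' Fit an equivalent-carbon-number retention model
#'
#' Ordinary (unweighted) least squares of retention time on total acyl
#' carbons and total double bonds.  A well-behaved reversed-phase system
#' gives a positive carbon coefficient and a negative double-bond
#' coefficient; the fit warns (but does not fail) when a coefficient has
#' the unexpected sign.
#'
#' @param observations Data frame with either a `name` column of shorthand
#'   names or the species columns of [parse_nape()], plus `rt_min`
#'   (observed retention time, minutes).
#' @return Object of class `retention_model` with fields `intercept`,
#'   `carbon_coeff` (min per carbon), `db_coeff` (min per double bond),
#'   `residual_sd` (min) and `n_fit`; supports [predict_rt()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_retention <- function(observations) {
  if (!is.data.frame(observations) || !"rt_min" %in% names(observations)) {
    abort("observations must be a data frame with an rt_min column")
  }
  species <- as_species(observations)
  tc <- total_chain_counts(species)
  d <- tibble(
    rt_min = observations$rt_min,
    total_c = tc$total_c,
    total_db = tc$total_db
  )
  if (nrow(d) < 3) abort("need at least 3 observations")
  if (length(unique(d$total_c)) < 2) {
    abort("rank-deficient design: no variation in total carbon number")
  }
  if (length(unique(d$total_db)) < 2) {
    abort("rank-deficient design: no variation in total double-bond count")
  }

  fit <- lm(rt_min ~ total_c + total_db, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) abort("rank-deficient design: collinear carbon/double-bond values")
  if (cf[["total_c"]] <= 0) {
    warn("carbon coefficient is not positive; retention should increase with chain length")
  }
  if (cf[["total_db"]] >= 0) {
    warn("double-bond coefficient is not negative; double bonds should reduce retention")
  }
  structure(
    list(
      intercept = unname(cf[["(Intercept)"]]),
      carbon_coeff = unname(cf[["total_c"]]),
      db_coeff = unname(cf[["total_db"]]),
      residual_sd = suppressWarnings(summary(fit)$sigma),
      n_fit = nrow(d),
      fit = fit
    ),
    class = "retention_model"
  )
}

# accept either shorthand names or an already-parsed species table
as_species <- function(x) {
  if (is.data.frame(x) && all(c("pe_carbons", "n_carbons") %in% names(x))) {
    x
  } else if (is.data.frame(x) && "name" %in% names(x)) {
    parse_nape(x$name)
  } else if (is.character(x)) {
    parse_nape(x)
  } else {
    abort("expected shorthand names or a parsed species table")
  }
}

#' Build a retention model from known coefficients
#'
#' Useful for simulation and for supplying literature coefficients without
#' refitting.
#'
#' @param intercept,carbon_coeff,db_coeff Model coefficients (minutes,
#'   min/carbon, min/double bond).
#' @param residual_sd Residual SD, minutes.
#' @return `retention_model` object (with `n_fit = 0`, marking it as
#'   constructed rather than fitted).
#' @export
retention_model <- function(intercept, carbon_coeff, db_coeff,
                            residual_sd = 0) {
  structure(
    list(
      intercept = intercept, carbon_coeff = carbon_coeff,
      db_coeff = db_coeff, residual_sd = residual_sd,
      n_fit = 0L, fit = NULL
    ),
    class = "retention_model"
  )
}

#' Predict retention times for NAPE species
#'
#' @param model `retention_model`.
#' @param species Species tibble or character vector of shorthand names.
#' @param run_length Run length, minutes; predictions are clipped to
#'   `[0, run_length]` with a warning when clipping occurs.
#' @return Numeric vector of predicted retention times, minutes.
#' @export
predict_rt <- function(model, species, run_length = 18) {
  stopifnot(inherits(model, "retention_model"))
  species <- as_species(species)
  tc <- total_chain_counts(species)
  rt <- model$intercept + model$carbon_coeff * tc$total_c +
    model$db_coeff * tc$total_db
  clipped <- rt < 0 | rt > run_length
  if (any(clipped)) {
    warn(paste0(
      sum(clipped), " predicted retention time(s) clipped to [0, ",
      run_length, "] min"
    ))
    rt <- pmin(pmax(rt, 0), run_length)
  }
  rt
}

#' Flag homologous-series retention outliers
#'
#' Species whose observed retention deviates from the model prediction by
#' more than `k` residual standard deviations; used to question
#' identifications that break the homologous-series pattern.
#'
#' @param model Fitted `retention_model`.
#' @param observations As in [fit_retention()].
#' @param k Residual-SD multiplier (default 3).
#' @return Tibble with `name`, `rt_min`, `predicted_min`, `residual_min`
#'   for flagged species only (zero rows when none).
#' @export
flag_rt_outliers <- function(model, observations, k = 3) {
  stopifnot(inherits(model, "retention_model"), k > 0)
  species <- as_species(observations)
  tc <- total_chain_counts(species)
  pred <- model$intercept + model$carbon_coeff * tc$total_c +
    model$db_coeff * tc$total_db
  resid <- observations$rt_min - pred
  out <- tibble(
    name = format_nape(species),
    rt_min = observations$rt_min,
    predicted_min = pred,
    residual_min = resid
  )
  # epsilon floor so an (effectively) exact fit never flags rounding error
  threshold <- max(k * model$residual_sd, sqrt(.Machine$double.eps))
  dplyr::filter(out, abs(.data$residual_min) > threshold)
}

#' @export
print.retention_model <- function(x, ...) {
  cat(
    "ECN retention model: rt =", signif(x$intercept, 5), "+",
    signif(x$carbon_coeff, 5), "* carbons",
    ifelse(x$db_coeff < 0, "-", "+"), signif(abs(x$db_coeff), 5),
    "* double bonds  (residual SD",
    signif(x$residual_sd, 3), "min, n =", x$n_fit, ")\n"
  )
  invisible(x)
}

#' @export
#' @method tidy retention_model
tidy.retention_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(
      term = c("(Intercept)", "total_c", "total_db"),
      estimate = c(x$intercept, x$carbon_coeff, x$db_coeff),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
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
#' @method glance retention_model
glance.retention_model <- function(x, ...) {
  tibble(
    r.squared = if (is.null(x$fit)) NA_real_ else
      suppressWarnings(summary(x$fit)$r.squared),
    sigma = x$residual_sd,
    nobs = x$n_fit
  )
}

#' @export
#' @method autoplot retention_model
autoplot.retention_model <- function(object, observations = NULL, ...) {
  if (is.null(observations) && !is.null(object$fit)) {
    d <- object$fit$model
    d <- tibble(
      rt_min = d$rt_min, total_c = d$total_c, total_db = d$total_db
    )
  } else if (!is.null(observations)) {
    species <- as_species(observations)
    tc <- total_chain_counts(species)
    d <- tibble(
      rt_min = observations$rt_min,
      total_c = tc$total_c, total_db = tc$total_db
    )
  } else {
    abort("no observations available to plot")
  }
  d$predicted <- object$intercept + object$carbon_coeff * d$total_c +
    object$db_coeff * d$total_db
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$total_c, y = .data$rt_min,
    colour = factor(.data$total_db)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), linetype = 2) +
    ggplot2::labs(
      x = "total acyl carbons", y = "retention time (min)",
      colour = "double bonds",
      title = "Equivalent-carbon-number retention model"
    )
}
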