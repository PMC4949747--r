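# Chromatographic peak detection and integration on single SRM traces.
#
# A "trace" here is a tibble with columns time_min and intensity for one
# transition, on a uniform time grid.

SNR_CAP <- 1e6 # sentinel reported when the baseline SD is exactly zero

#' Estimate baseline noise of a trace
#'
#' Robust baseline SD: `1.4826 * MAD` of the intensities outside an
#' optional exclusion interval (typically the detected peak).  Robustness
#' matters because the estimate is usually taken on a window that also
#' contains the peak.
#'
#' Because detector counts are clipped at zero, a baseline centred near
#' zero is strongly zero-inflated and the MAD collapses; the estimate is
#' therefore floored by the upper-quantile spread
#' `(Q60 - median) / 0.2533`, which equals the SD for Gaussian noise, is
#' insensitive to clipping from below, and stays clear of a peak
#' occupying the top of the intensity distribution.
#'
#' @param trace Tibble with `time_min`, `intensity` (one transition).
#' @param exclusion Optional `c(start, end)` minutes to exclude.
#' @return Baseline SD in counts (0 for a perfectly flat baseline).
#' @export
estimate_noise <- function(trace, exclusion = NULL) {
  int <- trace$intensity
  if (!is.null(exclusion)) {
    keep <- trace$time_min < exclusion[1] | trace$time_min > exclusion[2]
    int <- int[keep]
  }
  if (length(int) < 20) {
    abort("need at least 20 baseline points to estimate noise")
  }
  robust_noise_sd(int)
}

robust_noise_sd <- function(int) {
  mad_est <- mad(int, constant = 1.4826)
  # 0.2533 = qnorm(0.6): normalises the 60th-percentile spread to an SD
  quantile_est <- (stats::quantile(int, 0.60, names = FALSE) - median(int)) /
    0.2533471
  max(mad_est, quantile_est)
}

#' Detect peaks in an SRM trace
#'
#' Local maxima exceeding `baseline + 3 * SD` whose immediate neighbours
#' exceed `baseline + 2 * SD` (the neighbour rule suppresses single-sample
#' noise spikes); the baseline is the median intensity in the window and
#' the SD its 1.4826*MAD.  Peak bounds extend from the apex until the
#' signal falls back to `baseline + 1 * SD` or rises again (local
#' minimum).  The apex position is refined by parabolic interpolation of
#' the top three samples.  Peaks are returned ranked by area.
#'
#' @param trace Tibble with `time_min`, `intensity` (one transition).
#' @param window `c(start, end)` minutes to search (defaults to the full
#'   trace span).
#' @return Tibble with one row per peak: `rt_apex_min`, `height`, `area`
#'   (baseline-subtracted, intensity-seconds), `snr`, `rt_start_min`,
#'   `rt_end_min`, ordered by decreasing area.
#' @export
detect_peaks <- function(trace, window = NULL) {
  d <- as_tibble(trace)[, c("time_min", "intensity")]
  if (!is.null(window)) {
    d <- dplyr::filter(d, .data$time_min >= window[1], .data$time_min <= window[2])
  }
  n <- nrow(d)
  empty <- tibble(
    rt_apex_min = numeric(), height = numeric(), area = numeric(),
    snr = numeric(), rt_start_min = numeric(), rt_end_min = numeric()
  )
  if (n < 5) return(empty)

  int <- d$intensity
  tmin <- d$time_min
  baseline <- median(int)
  sdn <- robust_noise_sd(int)

  is_max <- c(FALSE, int[2:(n - 1)] > int[1:(n - 2)] &
                int[2:(n - 1)] >= int[3:n], FALSE)
  above <- int > baseline + 3 * sdn & int > baseline
  neigh <- c(FALSE, int[1:(n - 2)] > baseline + 2 * sdn, FALSE) &
    c(FALSE, int[3:n] > baseline + 2 * sdn, FALSE)
  cand <- which(is_max & above & neigh)
  if (length(cand) == 0) return(empty)

  floor_level <- baseline + sdn
  # walk outward from the apex until the signal falls back to the floor
  # (baseline + 1 SD) or a genuine valley: the running minimum has dropped
  # below half the apex height and the signal has risen again by more than
  # 2 SD on two consecutive points (single-point wiggles, and dips that
  # never leave the top half of the peak, are treated as noise)
  walk <- function(i, step) {
    j <- i
    min_val <- int[i]
    min_idx <- i
    rising <- 0L
    half_height <- baseline + (int[i] - baseline) / 2
    while (j + step >= 1 && j + step <= n) {
      j <- j + step
      if (int[j] <= floor_level) return(j)
      if (int[j] < min_val) {
        min_val <- int[j]
        min_idx <- j
        rising <- 0L
      } else if (int[j] > min_val + 2 * sdn && min_val <= half_height) {
        rising <- rising + 1L
        if (rising >= 2L || sdn == 0) return(min_idx)
      } else {
        rising <- 0L
      }
    }
    j
  }
  peaks <- purrr::map(cand, function(i) {
    l <- walk(i, -1L)
    r <- walk(i, 1L)
    if (r - l < 2) return(NULL)
    # a peak's apex must be the maximum of its extent; lesser candidates
    # (noise spikes on a flank) defer to the true apex claiming the region
    if (max(int[l:r]) > int[i]) return(NULL)

    # parabolic apex interpolation on (i-1, i, i+1)
    y1 <- int[i - 1]; y2 <- int[i]; y3 <- int[i + 1]
    denom <- y1 - 2 * y2 + y3
    shift <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
    shift <- max(min(shift, 0.5), -0.5)
    dt <- tmin[i + 1] - tmin[i]
    apex_t <- tmin[i] + shift * dt
    apex_h <- y2 - 0.25 * (y1 - y3) * shift

    area <- integrate_peak(d, c(tmin[l], tmin[r]))
    if (area <= 0) return(NULL)
    height <- apex_h - baseline
    if (height <= 0) return(NULL)
    tibble(
      rt_apex_min = apex_t,
      height = height,
      area = area,
      snr = if (sdn > 0) min(height / sdn, SNR_CAP) else SNR_CAP,
      rt_start_min = tmin[l],
      rt_end_min = tmin[r]
    )
  })
  out <- dplyr::bind_rows(peaks)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, dplyr::desc(.data$area))
  # merge duplicates: noise spikes riding on a peak produce candidate
  # apexes inside an already-accepted peak's bounds
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    inside <- out$rt_apex_min[i] >= out$rt_start_min[prior] &
      out$rt_apex_min[i] <= out$rt_end_min[prior]
    if (any(inside)) keep[i] <- FALSE
  }
  out[keep, ]
}

#' Integrate a trace between bounds
#'
#' Trapezoidal integral of the baseline-subtracted intensity, where the
#' baseline is the straight line between the intensities at the two
#' bounds.  Negative results (possible with noisy endpoints) are clipped
#' to zero and flagged via the `"clipped"` attribute.
#'
#' @param trace Tibble with `time_min`, `intensity`.
#' @param bounds `c(start, end)` minutes; must lie within the trace.
#' @return Area in intensity-seconds.
#' @export
integrate_peak <- function(trace, bounds) {
  if (bounds[2] < bounds[1]) abort("inverted integration bounds")
  d <- as_tibble(trace)
  sel <- d$time_min >= bounds[1] & d$time_min <= bounds[2]
  t <- d$time_min[sel]
  y <- d$intensity[sel]
  if (length(t) < 2) return(structure(0, clipped = FALSE))
  base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
  yc <- y - base
  ts <- t * 60
  area <- sum((yc[-1] + yc[-length(yc)]) / 2 * diff(ts))
  if (area < 0) structure(0, clipped = TRUE) else structure(area, clipped = FALSE)
}
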