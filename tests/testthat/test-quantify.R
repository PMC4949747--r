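# Peak detection, integration, two-transition confirmation and
# internal-standard quantification.

gaussian_fixture <- function(rt = 10, area = 100, sigma_s = 4, noise = 0,
                             span = c(8.5, 11.5), dt_s = 0.5, seed = 1) {
  t <- seq(span[1], span[2], by = dt_s / 60)
  amp <- area / (sigma_s * sqrt(2 * pi))
  y <- amp * exp(-((t - rt) * 60)^2 / (2 * sigma_s^2))
  if (noise > 0) {
    y <- withr::with_seed(seed, y + rnorm(length(t), 0, noise))
  }
  tibble::tibble(time_min = t, intensity = pmax(y, 0))
}

test_that("noise estimation is robust and handles the degenerate case", {
  flat <- gaussian_fixture(noise = 0)
  expect_equal(estimate_noise(flat, exclusion = c(9.5, 10.5)), 0)

  pure <- tibble::tibble(
    time_min = seq_len(2000) / 120,
    intensity = withr::with_seed(7, rnorm(2000, 100, 5))
  )
  est <- estimate_noise(pure)
  expect_rel_equal(est, 5, 0.10)

  expect_error(estimate_noise(pure[1:10, ]), "at least 20")
  expect_error(estimate_noise(pure, exclusion = c(-Inf, Inf)), "at least 20")
})

test_that("a single simulated peak is found at the true position", {
  tr <- gaussian_fixture(rt = 10, area = 100)
  peaks <- detect_peaks(tr)
  expect_equal(nrow(peaks), 1L)
  expect_lt(abs(peaks$rt_apex_min - 10), 0.5 / 60) # one sampling interval
  expect_rel_equal(peaks$area, 100, 0.005)
  expect_equal(peaks$snr, 1e6) # flat baseline -> capped sentinel
})

test_that("noise-only windows stay peak-free at the detection threshold", {
  n_windows <- 300
  fp <- withr::with_seed(123, {
    sum(purrr::map_int(seq_len(n_windows), function(i) {
      nrow(detect_peaks(noise_trace(360, sd = 1)))
    }) > 0)
  })
  expect_lt(fp / n_windows, 0.01)
})

test_that("partially resolved peaks are separated at the valley", {
  a <- gaussian_fixture(rt = 10, area = 100)
  b <- gaussian_fixture(rt = 10 + 20 / 60, area = 80) # 5 sigma apart
  tr <- tibble::tibble(
    time_min = a$time_min, intensity = a$intensity + b$intensity
  )
  peaks <- detect_peaks(tr)
  expect_equal(nrow(peaks), 2L)
  expect_equal(sort(peaks$rt_apex_min), c(10, 10 + 20 / 60),
               tolerance = 0.002)
})

test_that("trapezoidal integration satisfies its contracts", {
  tr <- gaussian_fixture(rt = 10, area = 1)
  expect_equal(integrate_peak(tr, c(8.5, 11.5)), 1, tolerance = 0.001,
               ignore_attr = TRUE)

  zero <- tibble::tibble(time_min = seq(0, 1, 1 / 120), intensity = 0)
  expect_equal(as.numeric(integrate_peak(zero, c(0, 1))), 0)
  expect_equal(as.numeric(integrate_peak(tr, c(10, 10))), 0)
  expect_error(integrate_peak(tr, c(11, 9)), "inverted")
})

test_that("confirmation names every failed criterion", {
  pk <- function(rt, area) {
    tibble::tibble(
      rt_apex_min = rt, height = area / 10, area = area, snr = 100,
      rt_start_min = rt - 0.2, rt_end_min = rt + 0.2
    )
  }
  none <- pk(10, 1)[0, ]

  clean <- confirm_species(pk(10, 100), pk(10.01, 35), expected_ratio = 0.35)
  expect_true(clean$detected)
  expect_length(clean$flags, 0)

  miss <- confirm_species(pk(10, 100), none, expected_ratio = 0.35)
  expect_false(miss$detected)
  expect_equal(miss$flags, "missing_qualifier")

  off_rt <- confirm_species(pk(10, 100), pk(10.3, 35), expected_ratio = 0.35)
  expect_false(off_rt$detected)
  expect_true("rt_mismatch" %in% off_rt$flags)

  bad_ratio <- confirm_species(pk(10, 100), pk(10, 70), expected_ratio = 0.35)
  expect_false(bad_ratio$detected)
  expect_equal(bad_ratio$flags, "ion_ratio_fail")

  expect_error(confirm_species(pk(10, 1), pk(10, 1), expected_ratio = 0),
               "positive")
})

test_that("equal analyte and IS areas give exactly 500 pmol/g", {
  method <- tiny_method()
  plan <- sample_plan(c("PE 38:2-N-16:0" = 50), seed = 2) # = IS amount
  traces <- simulate_sample(plan, method)
  res <- quantify_sample(traces, method)
  conc <- res$conc_pmol_per_g[res$species_name == "PE 38:2-N-16:0"]
  expect_equal(conc, 500, tolerance = 1e-6) # tail-truncation precision
})

test_that("a 2% response ratio sits at the 10 pmol/g quantification floor", {
  method <- tiny_method()
  plan <- sample_plan(c("PE 38:2-N-16:0" = 1), seed = 2) # area = 0.02 x IS
  traces <- simulate_sample(plan, method)
  res <- quantify_sample(traces, method)
  conc <- res$conc_pmol_per_g[res$species_name == "PE 38:2-N-16:0"]
  expect_equal(conc, 10, tolerance = 1e-6)
})

test_that("noiseless end-to-end recovery is within 0.5 percent", {
  names <- c("PE 38:2-N-16:0", "PE 36:2-N-18:0", "PE 34:1-N-16:0",
             "PE 40:6-N-22:6")
  method <- tiny_method(c(IS_NAME, names))
  amounts <- c(120, 35, 8, 260)
  rf <- c(0.8, 1.3, 1.0, 0.6, 1.1)
  plan <- sample_plan(
    setNames(amounts, names),
    response_factors = setNames(rf, c(names, IS_NAME)),
    ion_ratio = 0.35, seed = 6
  )
  traces <- simulate_sample(plan, method)
  res <- quantify_sample(traces, method)

  truth <- amounts / 0.1 * rf[1:4] / rf[5] # rf ratio biases one-point calib
  got <- res$conc_pmol_per_g[match(names, res$species_name)]
  expect_rel_equal(got, truth, 0.005)
  expect_true(all(res$detected))
})

test_that("an undetectable internal standard invalidates the sample", {
  method <- tiny_method()
  # IS amount zero: no IS peak anywhere
  plan <- sample_plan(c("PE 38:2-N-16:0" = 30), is_amount_pmol = 0, seed = 2)
  traces <- simulate_sample(plan, method)
  expect_error(quantify_sample(traces, method), "internal standard not detected")
})

test_that("concentrations are invariant under global area scaling", {
  method <- tiny_method(c(IS_NAME, "PE 38:2-N-16:0", "PE 36:2-N-18:0"))
  plan <- sample_plan(c("PE 38:2-N-16:0" = 80, "PE 36:2-N-18:0" = 15),
                      noise_sd = 0.01, seed = 14)
  traces <- simulate_sample(plan, method)
  res <- quantify_sample(traces, method)

  scaled <- dplyr::mutate(traces, intensity = intensity * 7.3)
  res_scaled <- quantify_sample(scaled, method)
  expect_equal(res_scaled$conc_pmol_per_g, res$conc_pmol_per_g,
               tolerance = 1e-9)
})

test_that("qualifier interference trips the ion-ratio gate", {
  method <- tiny_method(c(IS_NAME, "PE 38:2-N-16:0", "PE 36:2-N-18:0"))
  plan <- sample_plan(c("PE 38:2-N-16:0" = 40, "PE 36:2-N-18:0" = 40),
                      seed = 17)
  traces <- simulate_sample(plan, method)

  qual_id <- "PE 38:2-N-16:0|qualifier"
  qual_area <- 40 * 0.35
  dirty <- inject_interference(
    traces, method, qual_id, rt_offset_min = 0.3, area = 2 * qual_area
  )
  res <- quantify_sample(dirty, method)

  hit <- res[res$species_name == "PE 38:2-N-16:0", ]
  expect_false(hit$detected)
  expect_match(hit$flags, "ion_ratio_fail|rt_mismatch")
  expect_true(is.na(hit$conc_pmol_per_g))

  clean <- res[res$species_name == "PE 36:2-N-18:0", ]
  expect_true(clean$detected)
  expect_equal(clean$flags, "")
})

test_that("low signal-to-noise species are flagged below the LOQ", {
  method <- tiny_method()
  plan <- sample_plan(c("PE 38:2-N-16:0" = 2), noise_sd = 0.01, seed = 19)
  traces <- simulate_sample(plan, method)
  res <- quantify_sample(traces, method, snr_threshold = 1e5)
  hit <- res[res$species_name == "PE 38:2-N-16:0", ]
  expect_true(hit$detected)
  expect_match(hit$flags, "below_loq")
})
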