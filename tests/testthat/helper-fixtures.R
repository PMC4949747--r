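# Shared fixtures built in code.

IS_NAME <- "PE 18:1/18:1-N-19:0"

# the three co-eluting isobaric structural isomers used throughout
fig_trio_names <- c("PE 38:2-N-16:0", "PE 36:2-N-18:0", "PE 36:1-N-18:1")

# a well-behaved reversed-phase retention model for simulations
sim_rt_model <- function() retention_model(2.0, 0.30, -0.55)

tiny_method <- function(names = c(IS_NAME, "PE 38:2-N-16:0"), ...) {
  build_srm_method(parse_nape(names), sim_rt_model(), ...)
}

# noiseless single-analyte plan
clean_plan <- function(amounts = c("PE 38:2-N-16:0" = 30), seed = 1, ...) {
  sample_plan(amounts, seed = seed, ...)
}

# synthetic noise-only trace on the default acquisition grid
noise_trace <- function(n = 360, sd = 1, t0 = 10) {
  tibble::tibble(
    time_min = t0 + seq_len(n) * 0.5 / 60,
    intensity = rnorm(n, 0, sd)
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(
    all(abs(actual - expected) <= tol * abs(expected)),
    label = sprintf(
      "max relative error %.3g <= %.3g",
      max(abs(actual - expected) / abs(expected)), tol
    )
  )
}
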