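# Candidate enumeration, fragment ions, method construction, isobars,
# scheduling and transition-list export.

test_that("enumeration is the deduplicated cartesian product", {
  out <- enumerate_nape(c("36:1", "36:2", "38:4"), c("16:0", "18:0"))
  expect_equal(nrow(out), 6L)
  # duplicate pool entries change nothing
  out2 <- enumerate_nape(c("36:1", "36:2", "38:4", "36:1"),
                         c("16:0", "18:0", "16:0"))
  expect_identical(out2, out)
  # deterministic ordering by (C, D, n, dn)
  expect_identical(
    out$name,
    out[order(out$pe_carbons, out$pe_db, out$n_carbons, out$n_db), ]$name
  )
  expect_error(enumerate_nape(character(), "16:0"), "non-empty")
})

test_that("enumeration covers the co-eluting isomer trio", {
  out <- enumerate_nape(c("36:1", "36:2", "38:2"),
                        c("16:0", "18:0", "18:1"))
  expect_true(all(fig_trio_names %in% out$name))
})

test_that("molecular-level enumeration keeps O-acyl assignments", {
  out <- enumerate_nape(c("18:1/18:1", "16:0/18:1"), c("19:0", "20:4"),
                        level = "molecular")
  expect_equal(nrow(out), 4L)
  expect_true(all(out$level == "molecular"))
  expect_true("PE 18:1/18:1-N-19:0" %in% out$name)
  expect_error(
    enumerate_nape(c("36:1"), c("16:0"), level = "molecular"),
    "molecular"
  )
})

test_that("product ions carry the N-acyl chain only", {
  fr <- nape_fragments(parse_nape("PE 18:1/18:1-N-19:0"))
  expect_equal(fr$f1_formula, "C21H44NO5P")
  expect_equal(oracle_phospho_nae_composition(19, 0),
               c(C = 21, H = 44, N = 1, O = 5, P = 1))
  expect_equal(fr$f1_mz, 422.3029864903, tolerance = 1e-9)
  expect_equal(fr$f2_mz, 324.3260913956, tolerance = 1e-9)

  # same (n, dn), different PE bodies -> identical product pairs
  nm <- random_species_names(30, seed = 41)
  sp <- parse_nape(nm)
  fr_all <- nape_fragments(sp)
  key <- paste(sp$n_carbons, sp$n_db)
  for (k in unique(key)) {
    expect_equal(length(unique(fr_all$f1_mz[key == k])), 1L)
    expect_equal(length(unique(fr_all$f2_mz[key == k])), 1L)
  }
})

test_that("the two F2 bookkeepings differ by exactly one water", {
  sp <- parse_nape("PE 36:2-N-18:0")
  f2_h3po4 <- nape_fragments(sp, "H3PO4")$f2_mz
  f2_hpo3 <- nape_fragments(sp, "HPO3")$f2_mz
  h2o <- monoisotopic_mass(elemental_composition(H = 2, O = 1))
  expect_equal(f2_hpo3 - f2_h3po4, h2o, tolerance = 1e-12)
})

test_that("methods carry exactly two transitions per species", {
  m1 <- tiny_method("PE 38:2-N-16:0")
  expect_equal(nrow(m1), 2L)
  expect_setequal(m1$role, c("quantifier", "qualifier"))
  expect_equal(sum(m1$role == "quantifier"), 1L)

  many <- parse_nape(random_species_names(79, seed = 51))
  many <- dplyr::distinct(many, name, .keep_all = TRUE)
  mm <- suppressWarnings(build_srm_method(many, sim_rt_model()))
  expect_equal(nrow(mm), 2L * nrow(many))
  expect_true(all(mm$product_mz < mm$precursor_mz))
  expect_true(all(table(mm$species_name) == 2))
})

test_that("acquisition windows are centred on the expected retention time", {
  m <- build_srm_method(
    parse_nape("PE 36:1-N-16:0"),
    tibble::tibble(name = "PE 36:1-N-16:0", rt_min = 10.0),
    rt_window = 3
  )
  expect_equal(unique(m$rt_start_min), 8.5)
  expect_equal(unique(m$rt_end_min), 11.5)
})

test_that("species without a retention time are reported by name", {
  sp <- parse_nape(c("PE 36:1-N-16:0", "PE 36:2-N-16:0"))
  expect_error(
    build_srm_method(sp, tibble::tibble(name = "PE 36:1-N-16:0", rt_min = 9)),
    "PE 36:2-N-16:0"
  )
})

test_that("the isomer trio groups together and is product-ion resolvable", {
  iso <- find_isobars(parse_nape(fig_trio_names), mz_tolerance = 0.01)
  expect_equal(length(unique(iso$groups$isobar_group)), 1L)
  expect_equal(nrow(iso$pairs), 3L)
  expect_true(all(iso$pairs$resolvable))
})

test_that("a single double bond separates precursor groups", {
  iso <- find_isobars(parse_nape(c("PE 36:1-N-16:0", "PE 36:2-N-16:0")),
                      mz_tolerance = 0.01)
  expect_equal(length(unique(iso$groups$isobar_group)), 2L)
  expect_equal(nrow(iso$pairs), 0L)
})

test_that("identical transition sets are flagged ambiguous", {
  twice <- dplyr::bind_rows(
    parse_nape("PE 36:1-N-16:0"), parse_nape("PE 36:1-N-16:0")
  )
  iso <- find_isobars(twice, mz_tolerance = 0.01)
  expect_equal(length(unique(iso$groups$isobar_group)), 1L)
  expect_false(any(iso$pairs$resolvable))
})

test_that("zero tolerance groups species iff compositions are equal", {
  sp <- parse_nape(unique(c(
    fig_trio_names, random_species_names(40, seed = 61)
  )))
  sp <- dplyr::distinct(sp, name, .keep_all = TRUE)
  iso <- find_isobars(sp, mz_tolerance = 0)
  comp <- nape_composition(sp)
  key <- setNames(comp$formula, comp$name)
  grp <- setNames(iso$groups$isobar_group, iso$groups$name)
  for (i in seq_len(nrow(sp))) {
    for (j in seq_len(nrow(sp))) {
      same_comp <- key[[sp$name[i]]] == key[[sp$name[j]]]
      same_grp <- grp[[sp$name[i]]] == grp[[sp$name[j]]]
      expect_equal(same_comp, same_grp)
    }
  }
})

test_that("dwell time is the cycle time split over concurrent windows", {
  mk <- function(centers, width = 1, cycle = 1) {
    m <- tibble::tibble(
      species_name = paste0("s", seq_along(centers)),
      transition_id = paste0("t", seq_along(centers)),
      rt_center_min = centers,
      rt_start_min = centers - width / 2,
      rt_end_min = centers + width / 2
    )
    attr(m, "cycle_time_s") <- cycle
    m
  }
  st <- scheduling_stats(mk(c(2, 10)))
  expect_equal(st$transitions$dwell_ms, c(1000, 1000))
  st4 <- scheduling_stats(mk(c(5, 5, 5, 5)))
  expect_equal(st4$transitions$dwell_ms, rep(250, 4))
  expect_equal(st4$median_dwell_ms, 250)
})

test_that("concurrency matches brute-force interval counting", {
  withr::with_seed(71, {
    for (rep in 1:50) {
      n <- 50
      centers <- runif(n, 1, 17)
      width <- runif(n, 0.5, 4)
      m <- tibble::tibble(
        species_name = paste0("s", 1:n),
        transition_id = paste0("t", 1:n),
        rt_center_min = centers,
        rt_start_min = centers - width / 2,
        rt_end_min = centers + width / 2
      )
      attr(m, "cycle_time_s") <- 0.8
      st <- scheduling_stats(m, grid_step_min = 0.5)
      for (i in seq_len(nrow(st$concurrency))) {
        t <- st$concurrency$time_min[i]
        brute <- 0L
        for (j in 1:n) {
          if (m$rt_start_min[j] <= t && t <= m$rt_end_min[j]) brute <- brute + 1L
        }
        expect_equal(st$concurrency$n_active[i], brute)
      }
    }
  })
})

test_that("transition lists round-trip through CSV at 5-decimal precision", {
  m <- tiny_method(c(IS_NAME, "PE 38:2-N-16:0", "PE 36:2-N-18:0"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(m, path)

  lines <- readLines(path)
  expect_equal(length(lines), nrow(m) + 1L)
  expect_true(all(grepl(",\\d+\\.\\d{5},", lines[-1])))

  back <- read_transition_list(
    path, cycle_time_s = attr(m, "cycle_time_s")
  )
  expect_equal(back$species_name, m$species_name)
  expect_equal(back$transition_id, m$transition_id)
  expect_equal(back$precursor_mz, m$precursor_mz, tolerance = 1e-5)
  expect_equal(back$product_mz, m$product_mz, tolerance = 1e-5)
  expect_equal(back$rt_center_min, m$rt_center_min, tolerance = 1e-9)
  expect_equal(back$role, m$role)

  # a second write is byte-identical (stable ordering and formatting)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(m, path2)
  expect_identical(readLines(path), readLines(path2))
})
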