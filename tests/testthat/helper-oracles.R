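# Independent oracles used by the tests.  Deliberately implemented from a
# different starting point than the package: compositions are assembled
# from molecular building blocks (condensation chemistry) instead of the
# closed-form chain-count formula, and masses use a second atomic-mass
# table.

# -- structure-graph atom-count oracle --------------------------------------
# A NAPE is glycerol + two O-acyl fatty acids + phosphoric acid +
# ethanolamine + one N-acyl fatty acid, condensed with loss of 5 H2O
# (2 esters, 2 phosphoester bonds, 1 amide).

block <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  c(C = C, H = H, N = N, O = O, P = P)
}
GLYCEROL <- block(C = 3, H = 8, O = 3)
PHOSPHORIC_ACID <- block(H = 3, O = 4, P = 1)
ETHANOLAMINE <- block(C = 2, H = 7, N = 1, O = 1)
WATER <- block(H = 2, O = 1)

fatty_acid <- function(carbons, double_bonds) {
  block(C = carbons, H = 2 * carbons - 2 * double_bonds, O = 2)
}

oracle_nape_composition <- function(pe_carbons, pe_db, n_carbons, n_db,
                                    sn1 = NULL, sn2 = NULL) {
  if (is.null(sn1)) {
    # split totals arbitrarily; any split of the totals gives the same sum
    sn1 <- c(2, 0)
    sn2 <- c(pe_carbons - 2, pe_db)
  }
  GLYCEROL +
    fatty_acid(sn1[1], sn1[2]) +
    fatty_acid(sn2[1], sn2[2]) +
    PHOSPHORIC_ACID +
    ETHANOLAMINE +
    fatty_acid(n_carbons, n_db) -
    5 * WATER
}

oracle_diacyl_pe_composition <- function(pe_carbons, pe_db) {
  GLYCEROL +
    fatty_acid(2, 0) +
    fatty_acid(pe_carbons - 2, pe_db) +
    PHOSPHORIC_ACID +
    ETHANOLAMINE -
    4 * WATER
}

oracle_phospho_nae_composition <- function(n_carbons, n_db) {
  # phosphoethanolamine + amide-linked acyl
  PHOSPHORIC_ACID + ETHANOLAMINE + fatty_acid(n_carbons, n_db) - 2 * WATER
}

# -- second atomic-mass table -----------------------------------------------

ORACLE_MASS <- c(
  C = 12.0,
  H = 1.0078250321,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)
ORACLE_ELECTRON <- 0.0005485799

oracle_mass <- function(comp) {
  sum(comp[c("C", "H", "N", "O", "P")] * ORACLE_MASS)
}

oracle_mh_mz <- function(comp) {
  oracle_mass(comp) + ORACLE_MASS[["H"]] - ORACLE_ELECTRON
}

# -- random valid species ---------------------------------------------------

random_species_names <- function(n, molecular = FALSE, seed = NULL) {
  gen <- function() {
    acyl <- function() {
      c_ <- sample(2:26, 1)
      d_ <- sample(0:((c_ - 2) %/% 2), 1)
      sprintf("%d:%d", c_, d_)
    }
    if (molecular) {
      sprintf("PE %s/%s-N-%s", acyl(), acyl(), acyl())
    } else {
      c_ <- sample(4:44, 1)
      d_ <- sample(0:((c_ - 4) %/% 2), 1)
      sprintf("PE %d:%d-N-%s", c_, d_, acyl())
    }
  }
  if (!is.null(seed)) {
    withr::with_seed(seed, replicate(n, gen()))
  } else {
    replicate(n, gen())
  }
}

# -- closed-form OLS oracle -------------------------------------------------

ols_line_oracle <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - ym)^2)
  list(
    slope = slope, intercept = intercept,
    r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  )
}
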