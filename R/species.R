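# NAPE shorthand nomenclature: parsing, validation, canonical formatting.
#
# A NAPE is a diacyl-glycerophosphoethanolamine (the "PE body", summarised
# as total O-acyl carbons:double bonds) carrying a third, amide-linked
# N-acyl chain.  Shorthand names follow the PE-derived convention:
#
#   species level    "PE 36:1-N-16:0"         (O-acyl identities unknown)
#   molecular level  "PE 18:0/18:1-N-16:0"    (all chains known)
#
# Species are represented as tibbles with one row per species and integer
# columns for every chain; all downstream functions take and return this
# table, so calls chain with the pipe.

MAX_ACYL_CARBONS <- 40L

# ---- fatty acyl validation ------------------------------------------------

validate_acyl <- function(carbons, double_bonds, what, token) {
  ok <- !is.na(carbons) & !is.na(double_bonds) &
    carbons >= 2L & carbons <= MAX_ACYL_CARBONS &
    double_bonds >= 0L & double_bonds <= (carbons - 2L) %/% 2L
  if (!all(ok)) {
    bad <- token[!ok][1]
    abort(paste0(
      "invalid ", what, " chain '", bad, "': need 2-", MAX_ACYL_CARBONS,
      " carbons and 0 <= double bonds <= (carbons - 2) / 2"
    ))
  }
  invisible(TRUE)
}

validate_pe_body <- function(carbons, double_bonds, token) {
  ok <- !is.na(carbons) & !is.na(double_bonds) &
    carbons >= 4L & carbons <= 2L * MAX_ACYL_CARBONS &
    double_bonds >= 0L & double_bonds <= (carbons - 4L) %/% 2L
  if (!all(ok)) {
    bad <- token[!ok][1]
    abort(paste0(
      "invalid PE body '", bad, "': total O-acyl carbons must be >= 4 ",
      "(two chains of >= 2) and double bonds <= (carbons - 4) / 2"
    ))
  }
  invisible(TRUE)
}

# ---- parsing --------------------------------------------------------------

# Names pasted from typeset text carry non-ASCII hyphens and no-break
# spaces; normalise before matching.
normalize_name <- function(x) {
  x <- stringr::str_replace_all(x, "[‐‑‒–—−]", "-")
  x <- stringr::str_replace_all(x, "[   ]", " ")
  stringr::str_squish(x)
}

# One acyl token: "18:1" optionally with double-bond position/geometry
# annotation "(9Z,12Z)", which is accepted but discarded (mass arithmetic
# is position-blind).
ACYL_RE <- "(\\d+):(\\d+)(\\([^)]*\\))?"

SPECIES_RE <- paste0("^PE ", ACYL_RE, "-N-", ACYL_RE, "$")
MOLECULAR_RE <- paste0("^PE ", ACYL_RE, "/", ACYL_RE, "-N-", ACYL_RE, "$")

#' Parse NAPE shorthand names
#'
#' Parses shorthand NAPE names at species level (`"PE 36:1-N-16:0"`: total
#' O-acyl carbons:double bonds, then the N-acyl chain) or molecular-species
#' level (`"PE 18:0/18:1-N-16:0"`: both O-acyl chains explicit).  Unicode
#' hyphen variants, as produced by copying from typeset text, are accepted.
#' Double-bond position/geometry annotations such as `"18:1(9Z)"` are
#' accepted but dropped with a warning.
#'
#' @param x Character vector of shorthand names.
#' @return A species tibble with one row per name and columns `name`
#'   (canonical ASCII form), `level` (`"species"` or `"molecular"`),
#'   `pe_carbons`, `pe_db` (PE-body totals), `sn1_carbons`, `sn1_db`,
#'   `sn2_carbons`, `sn2_db` (`NA` at species level), `n_carbons`, `n_db`
#'   (the N-acyl chain).
#' @examples
#' parse_nape(c("PE 18:1/18:1-N-19:0", "PE 38:2-N-16:0"))
#' @export
parse_nape <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    abort("`x` must be a non-empty character vector of shorthand names")
  }
  raw <- x
  x <- normalize_name(x)
  if (any(stringr::str_detect(x, "\\("))) {
    warn("double-bond position/geometry annotations were discarded")
  }

  is_mol <- stringr::str_detect(x, MOLECULAR_RE)
  is_sp <- !is_mol & stringr::str_detect(x, SPECIES_RE)
  if (any(!is_mol & !is_sp)) {
    bad <- raw[!is_mol & !is_sp][1]
    abort(paste0(
      "cannot parse NAPE name '", bad,
      "': expected \"PE C:D-N-n:dn\" or \"PE c1:d1/c2:d2-N-n:dn\""
    ))
  }

  out <- tibble(
    name = NA_character_,
    level = ifelse(is_mol, "molecular", "species"),
    pe_carbons = NA_integer_, pe_db = NA_integer_,
    sn1_carbons = NA_integer_, sn1_db = NA_integer_,
    sn2_carbons = NA_integer_, sn2_db = NA_integer_,
    n_carbons = NA_integer_, n_db = NA_integer_
  )

  if (any(is_sp)) {
    m <- stringr::str_match(x[is_sp], SPECIES_RE)
    pe_c <- as.integer(m[, 2]); pe_d <- as.integer(m[, 3])
    n_c <- as.integer(m[, 5]); n_d <- as.integer(m[, 6])
    validate_pe_body(pe_c, pe_d, raw[is_sp])
    validate_acyl(n_c, n_d, "N-acyl", raw[is_sp])
    out$pe_carbons[is_sp] <- pe_c; out$pe_db[is_sp] <- pe_d
    out$n_carbons[is_sp] <- n_c; out$n_db[is_sp] <- n_d
  }
  if (any(is_mol)) {
    m <- stringr::str_match(x[is_mol], MOLECULAR_RE)
    s1c <- as.integer(m[, 2]); s1d <- as.integer(m[, 3])
    s2c <- as.integer(m[, 5]); s2d <- as.integer(m[, 6])
    n_c <- as.integer(m[, 8]); n_d <- as.integer(m[, 9])
    validate_acyl(s1c, s1d, "sn-1 O-acyl", raw[is_mol])
    validate_acyl(s2c, s2d, "sn-2 O-acyl", raw[is_mol])
    validate_acyl(n_c, n_d, "N-acyl", raw[is_mol])
    out$sn1_carbons[is_mol] <- s1c; out$sn1_db[is_mol] <- s1d
    out$sn2_carbons[is_mol] <- s2c; out$sn2_db[is_mol] <- s2d
    out$pe_carbons[is_mol] <- s1c + s2c
    out$pe_db[is_mol] <- s1d + s2d
    out$n_carbons[is_mol] <- n_c; out$n_db[is_mol] <- n_d
  }

  out$name <- format_nape(out)
  out
}

#' Format species as canonical shorthand names
#'
#' Inverse of [parse_nape()]: produces the canonical ASCII shorthand, so
#' `format_nape(parse_nape(x))` is the canonical form of `x` and
#' parse/format round-trip exactly on canonical names.
#'
#' @param species A species tibble (see [parse_nape()]).
#' @return Character vector of canonical names.
#' @export
format_nape <- function(species) {
  check_species_tbl(species)
  ifelse(
    species$level == "molecular",
    sprintf(
      "PE %d:%d/%d:%d-N-%d:%d",
      species$sn1_carbons, species$sn1_db,
      species$sn2_carbons, species$sn2_db,
      species$n_carbons, species$n_db
    ),
    sprintf(
      "PE %d:%d-N-%d:%d",
      species$pe_carbons, species$pe_db,
      species$n_carbons, species$n_db
    )
  )
}

check_species_tbl <- function(species) {
  need <- c(
    "level", "pe_carbons", "pe_db", "n_carbons", "n_db",
    "sn1_carbons", "sn1_db", "sn2_carbons", "sn2_db"
  )
  if (!is.data.frame(species) || !all(need %in% names(species))) {
    abort(paste0(
      "expected a species table with columns ",
      paste(need, collapse = ", "),
      " (see parse_nape())"
    ))
  }
  mol <- species$level == "molecular"
  if (any(mol)) {
    sum_ok <-
      species$sn1_carbons[mol] + species$sn2_carbons[mol] == species$pe_carbons[mol] &
      species$sn1_db[mol] + species$sn2_db[mol] == species$pe_db[mol]
    if (!all(sum_ok | is.na(sum_ok))) {
      abort("molecular species with O-acyl chains not summing to the PE body totals")
    }
  }
  invisible(species)
}

#' Elemental composition of NAPE species
#'
#' Adds the neutral elemental composition and monoisotopic mass to a
#' species table.  The composition of a NAPE with PE-body totals C:D and
#' N-acyl n:dn is C(C+n+5) H(2C-2D+2n-2dn+8) N O9 P, derived from the
#' structure (glycerol backbone, two O-acyl esters, phosphodiester to
#' ethanolamine, amide-linked N-acyl); it depends only on the chain
#' totals, never on the sn-position assignment, which is why distinct
#' molecular species can be isobaric.
#'
#' @param species Species tibble (see [parse_nape()]).
#' @return The input with added columns `elem_C`, `elem_H`, `elem_N`,
#'   `elem_O`, `elem_P`, `formula` and `neutral_mass` (Da, monoisotopic).
#' @examples
#' parse_nape("PE 18:1/18:1-N-19:0") |> nape_composition()
#' @export
nape_composition <- function(species) {
  check_species_tbl(species)
  C <- species$pe_carbons; D <- species$pe_db
  n <- species$n_carbons; dn <- species$n_db
  out <- dplyr::mutate(
    as_tibble(species),
    elem_C = C + n + 5L,
    elem_H = 2L * C - 2L * D + 2L * n - 2L * dn + 8L,
    elem_N = 1L,
    elem_O = 9L,
    elem_P = 1L
  )
  comps <- purrr::pmap(
    list(out$elem_C, out$elem_H, out$elem_N, out$elem_O, out$elem_P),
    function(c_, h_, n_, o_, p_) elemental_composition(c_, h_, n_, o_, p_)
  )
  out$formula <- purrr::map_chr(comps, format_formula)
  out$neutral_mass <- purrr::map_dbl(comps, monoisotopic_mass)
  out
}

#' Precursor m/z of NAPE species
#'
#' @param species Species tibble.
#' @param adduct Precursor adduct (`"M+H"` default, `"M+NH4"`, `"M-H"`).
#' @return The input with columns from [nape_composition()] plus
#'   `precursor_mz` and `adduct`.
#' @export
nape_precursor_mz <- function(species, adduct = "M+H") {
  adduct <- normalize_adduct(adduct)
  info <- adduct_info(adduct)
  out <- nape_composition(species)
  dplyr::mutate(
    out,
    adduct = adduct,
    precursor_mz = (.data$neutral_mass + info$shift) / abs(info$charge)
  )
}
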