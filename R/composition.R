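# Elemental composition arithmetic and monoisotopic mass / m/z conversion.
#
# Compositions are named integer vectors over the elements C, H, N, O, P --
# the only elements occurring in NAPE ions and the neutral losses handled
# here.  All masses are monoisotopic.

NAPE_ELEMENTS <- c("C", "H", "N", "O", "P")

# Monoisotopic atomic masses (u), CODATA/AME-style values.
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

ELECTRON_MASS <- 0.000548579909
PROTON_MASS <- ELEMENT_MASS[["H"]] - ELECTRON_MASS # 1.00727645...

#' Build an elemental composition vector
#'
#' Helper used throughout the package: a composition is a named integer
#' vector over the elements C, H, N, O and P.  Addition and subtraction of
#' compositions are ordinary vector arithmetic; [comp_subtract()] guards
#' against negative counts.
#'
#' @param C,H,N,O,P Non-negative integer element counts.
#' @return Named numeric vector of length 5.
#' @examples
#' elemental_composition(H = 2, O = 1) # water
#' @export
elemental_composition <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  out <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(out < 0)) {
    abort("element counts must be non-negative")
  }
  out
}

#' Subtract one composition from another
#'
#' @param x,y Compositions as returned by [elemental_composition()].
#' @return The composition `x - y`.  Errors if any element count would go
#'   negative (e.g. subtracting a neutral loss a fragment cannot afford).
#' @export
comp_subtract <- function(x, y) {
  out <- x - y
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    abort(paste0(
      "composition subtraction would give negative count for element(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

# Common small molecules used as neutral losses / adduct pieces.
COMP_H2O <- elemental_composition(H = 2, O = 1)
COMP_H3PO4 <- elemental_composition(H = 3, O = 4, P = 1)
COMP_HPO3 <- elemental_composition(H = 1, O = 3, P = 1)

#' Monoisotopic mass of a composition
#'
#' @param comp Composition vector from [elemental_composition()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(elemental_composition(H = 2, O = 1)) # 18.01056...
#' @export
monoisotopic_mass <- function(comp) {
  sum(comp[NAPE_ELEMENTS] * ELEMENT_MASS[NAPE_ELEMENTS])
}

# Supported electrospray adducts.  All singly charged; shifts include the
# electron mass so positive and negative modes are consistent to sub-mDa.
ADDUCTS <- list(
  "M+H" = list(charge = 1L, shift = PROTON_MASS),
  "M+NH4" = list(
    charge = 1L,
    shift = ELEMENT_MASS[["N"]] + 4 * ELEMENT_MASS[["H"]] - ELECTRON_MASS
  ),
  "M-H" = list(charge = -1L, shift = -(ELEMENT_MASS[["H"]] - ELECTRON_MASS))
)

#' Adduct mass shift and charge
#'
#' @param adduct One of `"M+H"`, `"M+NH4"`, `"M-H"`.
#' @return List with elements `charge` (signed integer) and `shift` (Da).
#' @export
adduct_info <- function(adduct) {
  adduct <- normalize_adduct(adduct)
  info <- ADDUCTS[[adduct]]
  if (is.null(info)) {
    abort(paste0(
      "unknown adduct '", adduct, "'; supported: ",
      paste(names(ADDUCTS), collapse = ", ")
    ))
  }
  info
}

# Accept the typographic minus variants that appear in typeset text.
normalize_adduct <- function(adduct) {
  stringr::str_replace_all(adduct, "[−‐‑–—]", "-")
}

#' m/z of an adduct ion
#'
#' @param comp Neutral composition ([elemental_composition()]).
#' @param adduct Adduct name, see [adduct_info()].
#' @return m/z of the singly charged ion: `(M + shift) / |charge|`.
#' @examples
#' ion_mz(elemental_composition(H = 2, O = 1), "M+H")
#' @export
ion_mz <- function(comp, adduct = "M+H") {
  info <- adduct_info(adduct)
  (monoisotopic_mass(comp) + info$shift) / abs(info$charge)
}

# Hill-ish formula string for display ("C60 H114 N O9 P" -> "C60H114NO9P").
format_formula <- function(comp) {
  parts <- purrr::map_chr(NAPE_ELEMENTS, function(el) {
    n <- comp[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  })
  paste(parts[parts != ""], collapse = "")
}
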