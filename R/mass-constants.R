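#' Monoisotopic element masses
#'
#' IUPAC/CODATA monoisotopic masses (u) for the elements supported by the
#' package, including carbon-13 (symbol `"13C"`) so that isotopically
#' labeled internal standards such as ring-labeled vanillin can be
#' expressed as ordinary formulas.
#'
#' @return Named numeric vector of monoisotopic masses in u.
#' @export
#' @examples
#' element_masses()[["O"]]
element_masses <- function() {
  c(
    C   = 12,
    `13C` = 13.0033548378,
    H   = 1.00782503207,
    N   = 14.0030740048,
    O   = 15.99491461956,
    S   = 31.97207100,
    Cl  = 34.96885268,
    F   = 18.99840322,
    P   = 30.97376163,
    Na  = 22.9897692809
  )
}

# electron rest mass in u
.electron_mass <- 0.00054857990907

# proton mass (H atom minus electron); subtracted when forming [M-H]- ions
.proton_mass <- 1.00782503207 - 0.00054857990907

#' Kendrick reference constants for the CH2 base
#'
#' The Kendrick rescaling maps the mass of the repeating CH2 unit onto its
#' nominal integer mass 14, so that all members of a CH2-homologue series
#' share the same mass defect. The exact mass is derived from the element
#' table (12 + 2 x 1.00782503 = 14.01565006 u) and agrees with the usual
#' rounded literature constant 14.01565 to well under 1e-5 u.
#'
#' @return List with elements `nominal` (14) and `exact` (CH2 monoisotopic
#'   mass in u).
#' @export
#' @examples
#' kendrick_basis()
kendrick_basis <- function() {
  m <- element_masses()
  list(nominal = 14, exact = unname(m[["C"]] + 2 * m[["H"]]))
}
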