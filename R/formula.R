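#' Parse a molecular formula string
#'
#' Accepts Hill-order or free-order element-count strings such as
#' `"C4H6O4"` or `"H2O"`. Carbon-13, used for isotopically labeled internal
#' standards, is written in brackets: `"[13C]6C2H8O3"` is phenyl-ring
#' labeled vanillin. Repeated element tokens accumulate.
#'
#' @param text A single formula string.
#' @return A `molform` object: named numeric vector of element counts in
#'   canonical Hill order (C, 13C, H, then remaining elements
#'   alphabetically).
#' @export
#' @examples
#' parse_formula("C4H6O4")    # succinic acid
#' parse_formula("C9H16O4")   # azelaic acid
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single formula string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) stop("empty formula string", call. = FALSE)
  text <- trimws(text)
  pattern <- "(\\[13C\\]|[A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    consumed <- paste(tokens, collapse = "")
    bad <- substr(text, nchar(consumed) + 1L, nchar(text))
    stop("cannot parse formula near '", bad, "' in '", text, "'",
         call. = FALSE)
  }
  sym <- sub("^(\\[13C\\]|[A-Z][a-z]?)[0-9]*$", "\\1", tokens)
  sym[sym == "[13C]"] <- "13C"
  cnt <- sub("^(\\[13C\\]|[A-Z][a-z]?)", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  known <- names(element_masses())
  if (any(!sym %in% known)) {
    stop("unknown element symbol '", sym[!sym %in% known][1L],
         "' in formula '", text, "'", call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  counts <- counts[counts > 0]
  as_molform(counts)
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named numeric vector or list of non-negative integer
#'   element counts; names must be supported element symbols (`"13C"` for
#'   carbon-13).
#' @return A `molform` object.
#' @export
#' @examples
#' as_molform(c(C = 4, H = 6, O = 4))
as_molform <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named", call. = FALSE)
  }
  known <- names(element_masses())
  if (any(!names(counts) %in% known)) {
    stop("unknown element symbol '",
         names(counts)[!names(counts) %in% known][1L], "'", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula has no atoms", call. = FALSE)
  # Hill order: C, 13C, H, then alphabetical
  lead <- intersect(c("C", "13C", "H"), names(counts))
  rest <- sort(setdiff(names(counts), lead))
  out <- as.numeric(counts[c(lead, rest)])
  names(out) <- c(lead, rest)
  structure(out, class = "molform")
}

#' Format a molecular formula as its canonical Hill-order string
#'
#' @param f A `molform` object.
#' @return Single string, e.g. `"C4H6O4"`; carbon-13 appears as `"[13C]n"`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molform"))
  sym <- names(f)
  sym[sym == "13C"] <- "[13C]"
  paste0(sym, ifelse(unclass(f) == 1, "", as.character(unclass(f))),
         collapse = "")
}

#' @export
format.molform <- function(x, ...) format_formula(x)

#' @export
print.molform <- function(x, ...) {
  cat("<molform>", format_formula(x), "\n")
  invisible(x)
}

#' @export
`+.molform` <- function(e1, e2) {
  stopifnot(inherits(e1, "molform"), inherits(e2, "molform"))
  all_sym <- union(names(e1), names(e2))
  v <- vapply(all_sym, function(s) {
    sum(c(unclass(e1)[s], unclass(e2)[s]), na.rm = TRUE)
  }, numeric(1))
  as_molform(v)
}

#' Count of an element in a formula (0 when absent)
#' @param f A `molform` object.
#' @param element Element symbol (use `"13C"` for carbon-13).
#' @return Integer count.
#' @export
element_count <- function(f, element) {
  stopifnot(inherits(f, "molform"))
  v <- unclass(f)[element]
  if (is.na(v)) 0 else unname(v)
}

#' Monoisotopic (exact) mass of a neutral molecule
#'
#' @param f A `molform` object or formula string.
#' @return Mass in u.
#' @export
#' @examples
#' monoisotopic_mass("C4H6O4")  # 118.02661
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molform"))
  m <- element_masses()
  sum(unclass(f) * m[names(f)])
}

#' m/z of the deprotonated molecular anion [M-H]-
#'
#' Negative-mode electrospray observes the deprotonated ion; its m/z is
#' the neutral monoisotopic mass minus a hydrogen atom plus one electron
#' (equivalently, minus a proton).
#'
#' @param f A `molform` object or formula string; must contain at least
#'   one hydrogen.
#' @return m/z in u at charge -1.
#' @export
#' @examples
#' mz_deprotonated("C4H6O4")  # 117.01933, succinic acid
#' mz_deprotonated("C5H8O4")  # 131.03498, glutaric acid
mz_deprotonated <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molform"))
  if (element_count(f, "H") < 1) {
    stop("formula ", format_formula(f),
         " has no hydrogen to abstract for [M-H]-", call. = FALSE)
  }
  monoisotopic_mass(f) - .proton_mass
}

#' Neutral monoisotopic mass from a measured [M-H]- m/z
#'
#' Inverse of [mz_deprotonated()]: adds back a proton.
#'
#' @param mz Measured m/z of the deprotonated anion.
#' @return Neutral mass in u.
#' @export
neutral_mass <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  mz + .proton_mass
}

#' Signed mass error in parts per million
#'
#' @param measured Measured m/z (or mass).
#' @param theoretical Theoretical m/z (or mass); must be positive.
#' @return Signed ppm error `(measured - theoretical) / theoretical * 1e6`.
#'   Vectorized.
#' @export
#' @examples
#' ppm_error(117.019457, 117.019340)  # about +1 ppm
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}

#' Elemental ratios used by Van Krevelen and Kroll diagrams
#'
#' Carbon-13 counts as carbon for all ratios.
#'
#' @param f A `molform` object or formula string with at least one carbon.
#' @return List with `o_c` (O/C), `h_c` (H/C) and `n_c` (carbon number).
#' @export
#' @examples
#' elemental_ratios("C4H6O4")  # O/C 1, H/C 1.5, n_c 4
elemental_ratios <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molform"))
  n_c <- element_count(f, "C") + element_count(f, "13C")
  if (n_c < 1) {
    stop("elemental ratios undefined: formula contains no carbon",
         call. = FALSE)
  }
  list(
    o_c = element_count(f, "O") / n_c,
    h_c = element_count(f, "H") / n_c,
    n_c = n_c
  )
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C - (H + halogens)/2 + (N + P)/2 + 1, with carbon-13 counted as
#' carbon. Even-electron [M-H]- ions of ordinary organic molecules have
#' integer, non-negative RDBE.
#'
#' @param f A `molform` object or formula string.
#' @return Numeric RDBE (may be half-integer for nitrogen-rule violations).
#' @export
rdbe <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molform"))
  cc <- element_count(f, "C") + element_count(f, "13C")
  hh <- element_count(f, "H") + element_count(f, "Cl") +
    element_count(f, "F")
  nn <- element_count(f, "N") + element_count(f, "P")
  cc - hh / 2 + nn / 2 + 1
}
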