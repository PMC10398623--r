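#' Kendrick mass (CH2 base)
#'
#' Rescales a neutral monoisotopic mass so that the CH2 repeating unit
#' has exactly integer mass 14: `KM = mass * 14 / m(CH2)`. Members of a
#' CH2-homologue series then differ by exactly 14 Kendrick units and
#' share a common mass defect.
#'
#' @param neutral_mass Neutral monoisotopic mass (u); positive. Measured
#'   [M-H]- m/z should be neutralized first with [neutral_mass()].
#' @param basis Kendrick reference, default [kendrick_basis()].
#' @return Kendrick mass (vectorized).
#' @export
#' @examples
#' kendrick_mass(monoisotopic_mass("C4H6O4"))
kendrick_mass <- function(neutral_mass, basis = kendrick_basis()) {
  if (any(neutral_mass <= 0)) stop("mass must be positive", call. = FALSE)
  neutral_mass * basis$nominal / basis$exact
}

#' Kendrick mass defect (CH2 base)
#'
#' `KMD = round(KM) - KM`, the signed distance of the Kendrick mass from
#' its nearest integer. Identical (to machine precision) for all members
#' of a CH2-homologue series.
#'
#' @inheritParams kendrick_mass
#' @return KMD in (-0.5, 0.5] (vectorized).
#' @export
#' @examples
#' kendrick_mass_defect(monoisotopic_mass("C4H6O4"))  # 0.1052, diacid series
kendrick_mass_defect <- function(neutral_mass, basis = kendrick_basis()) {
  km <- kendrick_mass(neutral_mass, basis)
  round(km) - km
}

#' Three-decimal homologue-series key for a KMD value
#'
#' Series are reported by their KMD truncated (not rounded) toward zero
#' at three decimals, the convention under which the linear dicarboxylic
#' acid series keys to 0.105 and the omega-hydroxy fatty acid series
#' CnH2nO3 to 0.068.
#'
#' @param kmd Kendrick mass defect value(s).
#' @param digits Decimals kept (default 3).
#' @return Truncated key (vectorized).
#' @export
kmd_series_key <- function(kmd, digits = 3) {
  trunc(kmd * 10^digits) / 10^digits
}

#' Detect CH2-homologue series among annotated features
#'
#' Groups features whose Kendrick mass defects agree within `kmd_tol`
#' and whose neutral masses differ by integer multiples of the exact CH2
#' mass within `ppm_tol`. Masses come from the assigned formula when
#' available, otherwise from the neutralized measured m/z. Singletons
#' are discarded.
#'
#' @param annotations Data frame with columns `id` and `mz`, optionally
#'   `formula` (from [annotate_features()]).
#' @param kmd_tol KMD grouping tolerance in Kendrick units (default
#'   0.0015, which separates the 0.105 and 0.068 series up to m/z 1000).
#' @param ppm_tol Tolerance on the CH2-multiple spacing in ppm.
#' @return Long data frame with one row per series member: `series_id`,
#'   `kmd_key`, `id`, `formula`, `neutral_mass`, `km`, `kmd`, `n_ch2`
#'   (CH2 repeats above the lightest member) and `base_formula`.
#' @export
detect_homologues <- function(annotations, kmd_tol = 0.0015, ppm_tol = 3) {
  stopifnot(is.data.frame(annotations), "id" %in% names(annotations))
  has_formula <- "formula" %in% names(annotations)
  mass <- vapply(seq_len(nrow(annotations)), function(i) {
    f <- if (has_formula) annotations$formula[i] else NA_character_
    if (!is.na(f)) monoisotopic_mass(f) else neutral_mass(annotations$mz[i])
  }, numeric(1))
  km <- kendrick_mass(mass)
  kmd <- round(km) - km
  empty <- data.frame(series_id = integer(0), kmd_key = numeric(0),
                      id = character(0), formula = character(0),
                      neutral_mass = numeric(0), km = numeric(0),
                      kmd = numeric(0), n_ch2 = integer(0),
                      base_formula = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(annotations) < 2) return(empty)
  # complete-linkage clustering on KMD: all pairwise gaps <= kmd_tol
  cl <- stats::cutree(stats::hclust(stats::dist(kmd), method = "complete"),
                      h = kmd_tol)
  ch2 <- kendrick_basis()$exact
  rows <- list()
  series_id <- 0L
  for (g in split(seq_along(cl), cl)) {
    if (length(g) < 2) next
    # connect members whose spacing is an integer >= 1 CH2 multiple
    o <- g[order(mass[g])]
    n <- length(o)
    comp <- seq_len(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- mass[o[j]] - mass[o[i]]
        k <- round(d / ch2)
        if (k >= 1 && abs(d - k * ch2) <= ppm_tol * 1e-6 * mass[o[j]]) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    for (cc in split(seq_len(n), comp)) {
      if (length(cc) < 2) next
      series_id <- series_id + 1L
      idx <- o[cc]
      base <- idx[which.min(mass[idx])]
      rows[[series_id]] <- data.frame(
        series_id = series_id,
        kmd_key = kmd_series_key(kmd[base]),
        id = as.character(annotations$id[idx]),
        formula = if (has_formula) annotations$formula[idx]
                  else NA_character_,
        neutral_mass = mass[idx],
        km = km[idx],
        kmd = kmd[idx],
        n_ch2 = as.integer(round((mass[idx] - mass[base]) / ch2)),
        base_formula = if (has_formula) annotations$formula[base]
                       else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
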