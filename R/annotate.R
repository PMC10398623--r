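#' Default element bounds for formula enumeration
#'
#' Upper counts per element used when assigning candidate formulas to
#' measured m/z values. The heteroatom set (N, S, Cl, F, P) covers the
#' composition classes encountered in alpine ice-core organics up to
#' m/z 1000.
#'
#' @return Named integer vector of maximum element counts.
#' @export
default_element_bounds <- function() {
  c(C = 40, H = 80, N = 2, O = 15, S = 2, Cl = 2, F = 2, P = 1)
}

# Grid of heteroatom counts (every element except H) within bounds,
# with per-row base masses. H is solved against the target window later.
.formula_grid <- function(bounds) {
  bounds <- bounds[bounds > 0 | names(bounds) == "H"]
  syms <- setdiff(names(bounds), "H")
  if (!"C" %in% syms) stop("element bounds must allow carbon", call. = FALSE)
  ranges <- lapply(syms, function(s) {
    if (s == "C") seq_len(bounds[[s]]) else 0:bounds[[s]]
  })
  names(ranges) <- syms
  g <- do.call(expand.grid, c(ranges, KEEP.OUT.ATTRS = FALSE))
  m <- element_masses()
  base <- as.numeric(as.matrix(g) %*% m[syms])
  list(grid = g, base = base, syms = syms)
}

#' Enumerate candidate molecular formulas for a measured [M-H]- m/z
#'
#' Exhaustively lists neutral formulas within per-element bounds whose
#' deprotonated-ion m/z falls within a ppm tolerance of the measured
#' value and which pass standard chemical filters: integer RDBE >= 0
#' (even-electron anion), 0 <= H/C <= 3, O/C <= 3, and at least one
#' abstractable hydrogen. Candidates are sorted by absolute ppm error,
#' ties broken by fewer heteroatoms and then lower RDBE.
#'
#' @param mz Measured m/z of the [M-H]- ion, within the instrument scan
#'   range 70-1000.
#' @param tol_ppm Mass tolerance in ppm (default 3, matching the observed
#'   instrumental accuracy window).
#' @param bounds Named vector of maximum element counts
#'   (default [default_element_bounds()]); must include C and H.
#' @return Data frame with columns `formula`, `mz_theoretical`, `ppm`,
#'   `rdbe` and one column per element count; zero rows when nothing
#'   matches.
#' @export
#' @examples
#' enumerate_formulas(117.01933)  # succinic acid, C4H6O4
enumerate_formulas <- function(mz, tol_ppm = 3,
                               bounds = default_element_bounds()) {
  if (length(bounds) == 0L || is.null(names(bounds))) {
    stop("`bounds` must be a non-empty named vector", call. = FALSE)
  }
  if (!all(c("C", "H") %in% names(bounds))) {
    stop("`bounds` must include C and H", call. = FALSE)
  }
  if (any(!names(bounds) %in% setdiff(names(element_masses()), "13C"))) {
    stop("unsupported element in bounds", call. = FALSE)
  }
  if (!is.numeric(mz) || length(mz) != 1L || mz < 70 || mz > 1000) {
    stop("m/z must lie within the instrument scan range [70, 1000]",
         call. = FALSE)
  }
  if (tol_ppm <= 0) stop("`tol_ppm` must be positive", call. = FALSE)
  fg <- .formula_grid(bounds)
  .enumerate_on_grid(mz, tol_ppm, fg, h_max = bounds[["H"]])
}

# Core enumeration against a precomputed heteroatom grid: the hydrogen
# count is solved from the residual mass (the H mass far exceeds any ppm
# window below m/z 1000, so at most one count can fit).
.enumerate_on_grid <- function(mz, tol_ppm, fg, h_max) {
  m <- element_masses()
  target <- neutral_mass(mz)           # neutral monoisotopic mass window
  lo <- neutral_mass(mz * (1 - tol_ppm * 1e-6))
  hi <- neutral_mass(mz * (1 + tol_ppm * 1e-6))
  h <- round((target - fg$base) / m[["H"]])
  mass <- fg$base + h * m[["H"]]
  ok <- h >= 1 & h <= h_max & mass >= lo & mass <= hi
  if (!any(ok)) return(.empty_candidates(fg$syms))
  g <- fg$grid[ok, , drop = FALSE]
  g$H <- h[ok]
  mass <- mass[ok]
  hal <- rowSums(g[, intersect(c("Cl", "F"), names(g)), drop = FALSE])
  np <- rowSums(g[, intersect(c("N", "P"), names(g)), drop = FALSE])
  rd <- g$C - (g$H + hal) / 2 + np / 2 + 1
  keep <- rd >= 0 & abs(rd - round(rd)) < 1e-9 &
    g$H / g$C <= 3 & g$O / g$C <= 3
  if (!any(keep)) return(.empty_candidates(fg$syms))
  g <- g[keep, , drop = FALSE]
  mass <- mass[keep]
  rd <- rd[keep]
  mz_theo <- mass - .proton_mass
  ppm <- ppm_error(mz, mz_theo)
  hetero <- rowSums(g[, setdiff(names(g), c("C", "H", "O")), drop = FALSE])
  ord <- order(abs(ppm), hetero, rd)
  g <- g[ord, , drop = FALSE]
  out <- data.frame(
    formula = vapply(seq_len(nrow(g)), function(i) {
      format_formula(as_molform(unlist(g[i, , drop = TRUE])))
    }, character(1)),
    mz_theoretical = mz_theo[ord],
    ppm = ppm[ord],
    rdbe = rd[ord],
    stringsAsFactors = FALSE
  )
  cbind(out, g, row.names = NULL)
}

.empty_candidates <- function(syms) {
  cols <- c(list(formula = character(0), mz_theoretical = numeric(0),
                 ppm = numeric(0), rdbe = numeric(0)),
            stats::setNames(rep(list(numeric(0)), length(syms) + 1L),
                            c(syms, "H")))
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

#' Composition class of a molecular formula
#'
#' CHO: only C, H, O (carbon required); CHNO: C, H, N, O with at least
#' one N; CHOS: C, H, O, S with at least one S; anything else (other
#' heteroatoms, or no formula at all for Level-5 features) is "other".
#' Carbon-13 counts as carbon.
#'
#' @param f A `molform`, a formula string, or `NA`/`NULL` for features
#'   without an assigned formula.
#' @return One of `"CHO"`, `"CHNO"`, `"CHOS"`, `"other"`.
#' @export
#' @examples
#' composition_class("C6H5NO3")   # CHNO (p-nitrophenol)
#' composition_class("C4H8O3S")   # CHOS
#' composition_class(NA)          # other (no formula)
composition_class <- function(f) {
  if (is.null(f) || (length(f) == 1L && is.na(f))) return("other")
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molform"))
  present <- names(f)
  present[present == "13C"] <- "C"
  present <- unique(present)
  has <- function(s) s %in% present
  if (!has("C")) return("other")
  if (all(present %in% c("C", "H", "O"))) return("CHO")
  if (all(present %in% c("C", "H", "N", "O")) && has("N")) return("CHNO")
  if (all(present %in% c("C", "H", "O", "S")) && has("S")) return("CHOS")
  "other"
}

#' Annotate a feature table with candidate molecular formulas
#'
#' Runs [enumerate_formulas()] on every feature and attaches the top
#' candidate, its composition class and a preliminary identification
#' level: 4 when exactly one formula survives the tolerance (unequivocal
#' formula), 3 when several tentative candidates remain, 5 when none
#' does. Levels 1-2 require reference standards or library spectra and
#' are assigned later by [identify_features()].
#'
#' @param features Data frame with columns `id`, `mz`, `rt`, `area` and
#'   optionally `sample` (see [read_feature_table()]).
#' @param tol_ppm Mass tolerance in ppm.
#' @param bounds Element bounds, as in [enumerate_formulas()].
#' @return Data frame with one row per feature: the feature columns plus
#'   `formula`, `ppm`, `rdbe`, `n_candidates`, `class`, `level`. The full
#'   per-feature candidate tables are kept in the list column
#'   `candidates`.
#' @export
annotate_features <- function(features, tol_ppm = 3,
                              bounds = default_element_bounds()) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  req <- c("id", "mz", "rt", "area")
  if (any(!req %in% names(features))) {
    stop("feature table lacks column(s): ",
         paste(setdiff(req, names(features)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(features$id)) {
    stop("duplicate feature id(s): ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "),
         call. = FALSE)
  }
  fg <- .formula_grid(bounds)
  cand <- lapply(features$mz, function(mzv) {
    if (mzv < 70 || mzv > 1000) {
      stop("feature m/z ", mzv, " outside scan range [70, 1000]",
           call. = FALSE)
    }
    .enumerate_on_grid(mzv, tol_ppm, fg, h_max = bounds[["H"]])
  })
  n_cand <- vapply(cand, nrow, integer(1))
  top <- function(col, default) {
    vapply(cand, function(d) if (nrow(d)) d[[col]][1L] else default,
           default)
  }
  out <- features
  out$formula <- top("formula", NA_character_)
  out$ppm <- top("ppm", NA_real_)
  out$rdbe <- top("rdbe", NA_real_)
  out$n_candidates <- n_cand
  out$class <- vapply(out$formula, composition_class, character(1),
                      USE.NAMES = FALSE)
  out$level <- ifelse(n_cand == 0L, 5L, ifelse(n_cand == 1L, 4L, 3L))
  out$candidates <- cand
  out
}
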