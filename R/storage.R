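#' Compare one analyte/feature between frozen and unfrozen storage
#'
#' Ratio and percent change of arm means, a two-sided Welch t-test when
#' both arms carry at least two replicates (paired t-test on request),
#' and flags for the 0.8-1.2 and 0.9-1.1 agreement bands (endpoints
#' inclusive).
#'
#' @param unfrozen,frozen Replicate values (areas or ng/g), at least one
#'   each, non-negative.
#' @param paired Use a paired t-test (requires equal lengths).
#' @param key Optional identifier carried into the result.
#' @return One-row data frame with `key`, `ratio` (frozen/unfrozen
#'   means), `pct_change`, `p_value`, `in_band_08_12`, `in_band_09_11`.
#'   A zero unfrozen mean yields `NA` ratio (flagged, not an error).
#' @export
#' @examples
#' compare_pair(rep(2.53e9, 3), rep(2.9019e9, 3))$ratio  # 1.147
compare_pair <- function(unfrozen, frozen, paired = FALSE,
                         key = NA_character_) {
  if (length(unfrozen) < 1 || length(frozen) < 1) {
    stop("need at least one replicate per arm", call. = FALSE)
  }
  if (any(c(unfrozen, frozen) < 0)) {
    stop("areas/concentrations must be non-negative", call. = FALSE)
  }
  mu <- mean(unfrozen); mf <- mean(frozen)
  ratio <- if (mu > 0) mf / mu else NA_real_
  pct <- if (mu > 0) 100 * (mf - mu) / mu else NA_real_
  p <- NA_real_
  if (length(unfrozen) >= 2 && length(frozen) >= 2 &&
      (stats::sd(unfrozen) > 0 || stats::sd(frozen) > 0)) {
    p <- if (paired) {
      if (length(unfrozen) != length(frozen)) {
        stop("paired test needs equal replicate counts", call. = FALSE)
      }
      stats::t.test(frozen, unfrozen, paired = TRUE)$p.value
    } else {
      stats::t.test(frozen, unfrozen, var.equal = FALSE)$p.value
    }
  }
  data.frame(
    key = key, ratio = ratio, pct_change = pct, p_value = p,
    in_band_08_12 = !is.na(ratio) && ratio >= 0.8 && ratio <= 1.2,
    in_band_09_11 = !is.na(ratio) && ratio >= 0.9 && ratio <= 1.1,
    stringsAsFactors = FALSE
  )
}

#' Storage comparison for a long paired table
#'
#' @param tbl Data frame with columns `key`, `arm` (`"unfrozen"` /
#'   `"frozen"`), `value`, and optionally `mode` (`"glass_vial"` /
#'   `"spe_cartridge"`); one comparison per key (and mode).
#' @param paired Passed to [compare_pair()].
#' @return Data frame of per-key comparisons, with `mode` retained when
#'   present.
#' @export
compare_storage <- function(tbl, paired = FALSE) {
  stopifnot(is.data.frame(tbl),
            all(c("key", "arm", "value") %in% names(tbl)))
  if (any(!tbl$arm %in% c("unfrozen", "frozen"))) {
    stop("`arm` must be 'unfrozen' or 'frozen'", call. = FALSE)
  }
  has_mode <- "mode" %in% names(tbl)
  grp <- if (has_mode) interaction(tbl$key, tbl$mode, drop = TRUE)
         else tbl$key
  out <- do.call(rbind, lapply(split(tbl, grp), function(d) {
    u <- d$value[d$arm == "unfrozen"]
    f <- d$value[d$arm == "frozen"]
    r <- if (length(u) == 0 || length(f) == 0) {
      # feature absent from one arm (e.g. lost on freezing): flagged
      data.frame(key = as.character(d$key[1]), ratio = NA_real_,
                 pct_change = NA_real_, p_value = NA_real_,
                 in_band_08_12 = FALSE, in_band_09_11 = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      compare_pair(u, f, paired = paired, key = as.character(d$key[1]))
    }
    if (has_mode) r$mode <- as.character(d$mode[1])
    r
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of storage ratios inside an agreement band
#'
#' @param ratios Numeric frozen/unfrozen ratios (`NA` entries dropped
#'   from the denominator).
#' @param band Length-2 numeric `c(lo, hi)`, endpoints inclusive.
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' band_census(c(0.85, 1.0, 1.3), c(0.8, 1.2))  # 2/3
band_census <- function(ratios, band = c(0.8, 1.2)) {
  if (length(ratios) == 0) stop("no ratios supplied", call. = FALSE)
  if (length(band) != 2 || band[1] > band[2]) {
    stop("`band` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0) return(NA_real_)
  mean(r >= band[1] & r <= band[2])
}

#' Features found only in the unfrozen sample
#'
#' @param unfrozen_keys,frozen_keys Feature keys detected in each arm.
#' @return List with `count` and `keys` (set difference
#'   unfrozen minus frozen).
#' @export
unique_to_unfrozen <- function(unfrozen_keys, frozen_keys) {
  k <- setdiff(unfrozen_keys, frozen_keys)
  list(count = length(k), keys = k)
}
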