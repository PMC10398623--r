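#' Methodological detection limit from procedural blanks
#'
#' MDL = 3 times the sample standard deviation of procedural blank
#' concentrations.
#'
#' @param blank_concentrations Numeric vector of blank concentrations
#'   (ng/g), at least 2 values (the validation design uses n = 14).
#' @return MDL in ng/g.
#' @export
#' @examples
#' mdl(rep(0.005, 14))  # identical blanks: 0
mdl <- function(blank_concentrations) {
  if (length(blank_concentrations) < 2) {
    stop("need at least 2 blank measurements", call. = FALSE)
  }
  3 * stats::sd(blank_concentrations)
}

#' Instrumental accuracy and precision from QC replicates
#'
#' Accuracy is the mean relative bias (O - T)/T expressed in percent;
#' precision is the relative standard deviation (%RSD) of the observed
#' values.
#'
#' @param measured Observed QC concentrations at one level (>= 2
#'   replicates).
#' @param nominal True (spiked) QC concentration; non-zero.
#' @return List with `accuracy` (%) and `precision` (%RSD).
#' @export
#' @examples
#' accuracy_precision(c(10.4, 10.4, 10.4), 10)  # +4 %, 0 %RSD
accuracy_precision <- function(measured, nominal) {
  if (nominal == 0) stop("nominal concentration must be non-zero",
                         call. = FALSE)
  if (length(measured) < 2) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  list(
    accuracy = mean((measured - nominal) / nominal) * 100,
    precision = 100 * stats::sd(measured) / mean(measured)
  )
}

#' Matrix effect between clean-solvent and matrix-matched calibrations
#'
#' Percent difference of response factors:
#' `(RF_UPW - RF_matrix) / RF_UPW * 100`. Positive values indicate
#' ionization suppression in the matrix.
#'
#' @param rf_upw Response factor of the curve prepared in ultrapure
#'   water; positive.
#' @param rf_matrix Response factor of the curve prepared in the SPE
#'   elution matrix.
#' @return Matrix effect in percent (vectorized over pairs).
#' @export
#' @examples
#' matrix_effect(1.0, 0.91)  # 9 %
matrix_effect <- function(rf_upw, rf_matrix) {
  if (any(rf_upw <= 0)) {
    stop("UPW response factor must be positive", call. = FALSE)
  }
  (rf_upw - rf_matrix) / rf_upw * 100
}

#' Spike recovery, aggregated per level and overall
#'
#' Recovery = 100 * measured / nominal. When several spike levels are
#' supplied, a one-way ANOVA tests whether recovery depends on level
#' (the method expects level-independent recoveries).
#'
#' @param measured Measured concentrations of spiked samples (ng/g).
#' @param nominal Nominal spiked concentrations, same length (non-zero).
#' @param level Optional grouping factor (spike level labels); defaults
#'   to `nominal`.
#' @return List with `mean`, `sd` (overall %), `per_level` (data frame
#'   of level, mean, sd, n) and `p_level` (ANOVA p-value for a level
#'   effect; `NA` with fewer than 2 levels).
#' @export
#' @examples
#' recovery(c(0.87, 0.85), c(1, 1))  # 86 % mean
recovery <- function(measured, nominal, level = NULL) {
  if (any(nominal == 0)) stop("nominal concentration must be non-zero",
                              call. = FALSE)
  if (length(measured) != length(nominal)) {
    stop("`measured` and `nominal` lengths differ", call. = FALSE)
  }
  if (length(measured) < 2) stop("need at least 2 replicates",
                                 call. = FALSE)
  if (is.null(level)) level <- nominal
  pct <- 100 * measured / nominal
  per <- do.call(rbind, lapply(split(pct, level), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  per <- cbind(level = rownames(per), per, stringsAsFactors = FALSE)
  rownames(per) <- NULL
  p_level <- NA_real_
  if (length(unique(level)) >= 2 && all(per$n >= 2)) {
    p_level <- summary(stats::aov(pct ~ factor(level)))[[1]][1, "Pr(>F)"]
  }
  list(mean = mean(pct), sd = stats::sd(pct), per_level = per,
       p_level = p_level)
}

#' Assemble a per-analyte method-validation report
#'
#' Combines calibration curves, QC runs, procedural blanks, matrix
#' curves and spike recoveries into one table mirroring a standard
#' method-performance summary (RF, R2, LOD, MDL, accuracy, precision,
#' matrix effect, recovery).
#'
#' @param calibration Data frame with `analyte`, `concentration`,
#'   `analyte_area`, `is_area`.
#' @param qc Data frame with `analyte`, `nominal`, `measured`.
#' @param blanks Data frame with `analyte`, `concentration`.
#' @param spikes Data frame with `analyte`, `nominal`, `measured`.
#' @param matrix_calibration Optional data frame like `calibration` but
#'   acquired in the SPE elution matrix.
#' @param injection_volume_ul Injection volume for the LOD conversion.
#' @return Data frame, one row per analyte and QC level.
#' @export
validation_report <- function(calibration, qc, blanks, spikes,
                              matrix_calibration = NULL,
                              injection_volume_ul = 20) {
  analytes <- unique(calibration$analyte)
  rows <- lapply(analytes, function(an) {
    curve <- fit_calibration(calibration[calibration$analyte == an, ],
                             analyte = an)
    l <- lod(curve, injection_volume_ul)
    m <- mdl(blanks$concentration[blanks$analyte == an])
    me <- NA_real_
    if (!is.null(matrix_calibration)) {
      mc <- matrix_calibration[matrix_calibration$analyte == an, ]
      if (nrow(mc)) {
        me <- matrix_effect(curve$slope,
                            fit_calibration(mc, analyte = an)$slope)
      }
    }
    sp <- spikes[spikes$analyte == an, ]
    rec <- recovery(sp$measured, sp$nominal)
    qca <- qc[qc$analyte == an, ]
    do.call(rbind, lapply(unique(qca$nominal), function(lev) {
      ap <- accuracy_precision(qca$measured[qca$nominal == lev], lev)
      data.frame(
        analyte = an, rf = curve$slope, r2 = curve$r2,
        lod_pg = l$pg, mdl = m, qc_level = lev,
        accuracy = ap$accuracy, precision = ap$precision,
        matrix_effect = me, recovery_mean = rec$mean,
        recovery_sd = rec$sd, recovery_p_level = rec$p_level,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
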