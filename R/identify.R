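#' Assign a Schymanski-style identification confidence level
#'
#' Level 1: a reference standard with the same molecular formula matches
#' within the retention-time tolerance (strictly less than `rt_tol`) and
#' spectral evidence (library match or standard-spectrum similarity at
#' or above `score_threshold`) supports the identity. Level 2: strong
#' spectral match but no RT confirmation (probable structure, e.g. an
#' isomer of the standard). Level 3: tentative candidates only - a weak
#' spectral match (at or above `level3_floor`) or several formula
#' candidates within tolerance. Level 4: a single unequivocal formula.
#' Level 5: exact mass only.
#'
#' @param formula Assigned formula string (`NA` when none).
#' @param rt Feature retention time (min).
#' @param n_candidates Number of formula candidates within tolerance.
#' @param standards Data frame of reference standards with columns
#'   `name`, `formula`, `rt`; optionally a list column `spectrum`.
#' @param library_score Optional library best-match score (0-100).
#' @param query_spectrum Optional measured `spectrum`; compared with a
#'   matching standard's spectrum when available.
#' @param rt_tol RT tolerance in minutes (default 0.1); the comparison
#'   is strict (`< rt_tol`).
#' @param score_threshold Minimum spectral score for structure-level
#'   evidence (default 80).
#' @param level3_floor Minimum score counted as a tentative (Level 3)
#'   match (default 50).
#' @param rt_only_level1 When `TRUE`, an RT match alone confirms Level 1
#'   if no spectral information exists at all.
#' @param frag_tol Fragment tolerance for standard-spectrum comparison.
#' @return List with `level`, `matched_standard`, `match_score`,
#'   `delta_rt`.
#' @export
assign_level <- function(formula, rt, n_candidates,
                         standards = NULL, library_score = NA_real_,
                         query_spectrum = NULL, rt_tol = 0.1,
                         score_threshold = 80, level3_floor = 50,
                         rt_only_level1 = FALSE, frag_tol = 0.005) {
  if (!is.numeric(rt_tol) || rt_tol <= 0) {
    stop("`rt_tol` must be positive", call. = FALSE)
  }
  matched <- NA_character_
  delta_rt <- NA_real_
  score <- if (is.null(library_score)) NA_real_ else library_score
  std_hit <- NULL
  if (!is.na(formula) && !is.null(standards) && nrow(standards) > 0) {
    canon <- vapply(standards$formula, function(s) {
      format_formula(parse_formula(s))
    }, character(1), USE.NAMES = FALSE)
    hits <- which(canon == format_formula(parse_formula(formula)))
    if (length(hits)) {
      d <- abs(standards$rt[hits] - rt)
      best <- hits[which.min(d)]
      std_hit <- standards[best, , drop = FALSE]
      matched <- standards$name[best]
      delta_rt <- min(d)
      if (!is.null(query_spectrum) && "spectrum" %in% names(standards) &&
          !is.null(standards$spectrum[[best]])) {
        s_std <- spectral_similarity(query_spectrum,
                                     standards$spectrum[[best]], frag_tol)
        score <- max(score, s_std, na.rm = TRUE)
      }
    }
  }
  spectral_ok <- !is.na(score) && score >= score_threshold
  no_spectral_info <- is.na(score)
  level <- if (!is.null(std_hit) && delta_rt < rt_tol &&
               (spectral_ok || (rt_only_level1 && no_spectral_info))) {
    1L
  } else if (spectral_ok) {
    2L
  } else if ((!is.na(score) && score >= level3_floor) ||
             (!is.na(formula) && n_candidates >= 2)) {
    3L
  } else if (!is.na(formula) && n_candidates == 1) {
    4L
  } else {
    5L
  }
  list(level = level, matched_standard = matched,
       match_score = if (is.na(score)) NA_real_ else score,
       delta_rt = delta_rt)
}

#' Identify annotated features against reference standards
#'
#' Vectorized wrapper around [assign_level()]: refines the preliminary
#' levels of [annotate_features()] using reference standards, library
#' scores and (optionally) measured MS/MS spectra.
#'
#' @param annotations Output of [annotate_features()]; an optional
#'   numeric column `library_score` supplies per-feature library
#'   best-match scores.
#' @param standards Reference standard table (see [assign_level()]).
#' @param spectra Optional named list of `spectrum` objects keyed by
#'   feature id.
#' @inheritParams assign_level
#' @return `annotations` with columns `level`, `matched_standard`,
#'   `match_score`, `delta_rt` replaced/added.
#' @export
identify_features <- function(annotations, standards = NULL,
                              spectra = NULL, rt_tol = 0.1,
                              score_threshold = 80, level3_floor = 50,
                              rt_only_level1 = FALSE, frag_tol = 0.005) {
  stopifnot(is.data.frame(annotations))
  lib <- if ("library_score" %in% names(annotations)) {
    annotations$library_score
  } else {
    rep(NA_real_, nrow(annotations))
  }
  res <- lapply(seq_len(nrow(annotations)), function(i) {
    assign_level(
      formula = annotations$formula[i], rt = annotations$rt[i],
      n_candidates = annotations$n_candidates[i], standards = standards,
      library_score = lib[i],
      query_spectrum = if (!is.null(spectra))
        spectra[[as.character(annotations$id[i])]] else NULL,
      rt_tol = rt_tol, score_threshold = score_threshold,
      level3_floor = level3_floor, rt_only_level1 = rt_only_level1,
      frag_tol = frag_tol
    )
  })
  annotations$level <- vapply(res, `[[`, integer(1), "level")
  annotations$matched_standard <-
    vapply(res, `[[`, character(1), "matched_standard")
  annotations$match_score <- vapply(res, `[[`, numeric(1), "match_score")
  annotations$delta_rt <- vapply(res, `[[`, numeric(1), "delta_rt")
  annotations
}

#' Count identifications per confidence level
#'
#' @param levels Integer vector of levels 1-5 (or a data frame with a
#'   `level` column).
#' @return Named integer vector of counts for levels "1" through "5";
#'   sums to the number of inputs.
#' @export
#' @examples
#' level_census(c(1, 1, 4, 2, 5))
level_census <- function(levels) {
  if (is.data.frame(levels)) levels <- levels$level
  if (length(levels) && any(!levels %in% 1:5)) {
    stop("levels must be integers 1-5", call. = FALSE)
  }
  tab <- table(factor(levels, levels = 1:5))
  stats::setNames(as.integer(tab), names(tab))
}
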