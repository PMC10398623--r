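#' Pipeline configuration
#'
#' Collects the tolerances and thresholds of every stage into one list
#' that round-trips through JSON ([write_config()] / [read_config()]).
#'
#' @param tol_ppm Formula-assignment mass tolerance (ppm).
#' @param kmd_tol Homologue-series KMD grouping tolerance (Kendrick u).
#' @param rt_tol Retention-time tolerance for Level-1 confirmation (min).
#' @param frag_tol MS/MS fragment matching tolerance (u).
#' @param score_threshold Spectral score for structure-level evidence.
#' @param level3_floor Minimum spectral score for a tentative match.
#' @param kendrick_area_min Area filter for the Kendrick diagram.
#' @param injection_volume_ul Injection volume for the LOD conversion.
#' @param bounds Element bounds for enumeration.
#' @param seed Seed for the synthetic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tol_ppm = 3, kmd_tol = 0.0015, rt_tol = 0.1,
                            frag_tol = 0.005, score_threshold = 80,
                            level3_floor = 50, kendrick_area_min = 5e6,
                            injection_volume_ul = 20,
                            bounds = default_element_bounds(),
                            seed = 42) {
  cfg <- as.list(environment())
  if (any(c(cfg$tol_ppm, cfg$kmd_tol, cfg$rt_tol, cfg$frag_tol) <= 0)) {
    stop("all tolerances must be positive", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$bounds <- as.list(x$bounds)  # keep element names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "bounds")])
  cfg$bounds <- unlist(raw$bounds)
  cfg
}

#' Run the full hybrid screening pipeline on a synthetic bundle
#'
#' Executes every stage end to end with the synthetic-fixture generator
#' as input source: untargeted simulation, formula annotation, homologue
#' mining, diagram export, identification census, targeted
#' calibration/validation, sample quantification, and the storage
#' comparison. All outputs are written as delimited text into `outdir`;
#' the run is fully determined by `cfg$seed`.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param standards Optional reference-standard table for the
#'   identification stage.
#' @return Invisible list of all stage outputs.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir,
                         standards = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- synth_config(seed = cfg$seed)
  out <- list()

  # untargeted branch
  unt <- simulate_untargeted(scfg)
  ann <- annotate_features(unt$features, tol_ppm = cfg$tol_ppm,
                           bounds = cfg$bounds)
  ann <- identify_features(ann, standards = standards,
                           rt_tol = cfg$rt_tol,
                           score_threshold = cfg$score_threshold,
                           level3_floor = cfg$level3_floor,
                           frag_tol = cfg$frag_tol)
  series <- detect_homologues(ann, kmd_tol = cfg$kmd_tol,
                              ppm_tol = cfg$tol_ppm)
  diagrams <- diagram_tables(ann, kendrick_area_min = cfg$kendrick_area_min)
  census <- level_census(ann$level)
  out$features <- unt$features
  out$truth <- unt$truth
  out$annotations <- ann
  out$series <- series
  out$diagrams <- diagrams
  out$census <- census

  # targeted branch
  cal <- simulate_calibration(scfg)
  report <- validation_report(cal$calibration, cal$qc, cal$blanks,
                              cal$spikes, cal$matrix_calibration,
                              injection_volume_ul = cfg$injection_volume_ul)
  quant <- do.call(rbind, lapply(unique(cal$samples$analyte), function(an) {
    d <- cal$samples[cal$samples$analyte == an, ]
    curve <- fit_calibration(
      cal$calibration[cal$calibration$analyte == an, ], analyte = an)
    rec <- report$recovery_mean[report$analyte == an][1]
    m <- report$mdl[report$analyte == an][1]
    cbind(analyte = an,
          quantify_sample(d$analyte_area, d$is_area, curve,
                          recovery_pct = rec, mdl = m,
                          sample = d$sample))
  }))
  out$validation <- report
  out$quantified <- quant

  # storage branch
  sto <- simulate_storage(scfg)
  out$storage_untargeted <- compare_storage(sto$untargeted)
  out$storage_targeted <- compare_storage(sto$targeted |>
    transform(key = analyte))
  present_frozen <- unique(
    sto$untargeted$key[sto$untargeted$arm == "frozen" &
                         sto$untargeted$mode == "spe_cartridge"])
  present_unfrozen <- unique(
    sto$untargeted$key[sto$untargeted$arm == "unfrozen" &
                         sto$untargeted$mode == "spe_cartridge"])
  out$storage_unique <- unique_to_unfrozen(present_unfrozen,
                                           present_frozen)

  # exports
  write_table(out$features, file.path(outdir, "features.csv"))
  write_table(out$truth, file.path(outdir, "truth.csv"))
  write_table(out$annotations, file.path(outdir, "annotations.csv"))
  write_table(out$series, file.path(outdir, "homologue_series.csv"))
  for (nm in names(diagrams)) {
    write_table(diagrams[[nm]], file.path(outdir,
                                          paste0("diagram_", nm, ".csv")))
  }
  write_table(data.frame(level = names(census), n = as.integer(census)),
              file.path(outdir, "level_census.csv"))
  write_table(report, file.path(outdir, "validation_report.csv"))
  write_table(quant, file.path(outdir, "quantified_samples.csv"))
  write_table(out$storage_untargeted,
              file.path(outdir, "storage_untargeted.csv"))
  write_table(out$storage_targeted,
              file.path(outdir, "storage_targeted.csv"))
  write_config(cfg, file.path(outdir, "config.json"))
  invisible(out)
}
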