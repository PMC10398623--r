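test_that("generators are deterministic for a fixed seed", {
  cfg <- synth_config(seed = 123, n_features = 50)
  expect_identical(simulate_untargeted(cfg), simulate_untargeted(cfg))
  expect_identical(simulate_calibration(cfg), simulate_calibration(cfg))
  expect_identical(simulate_storage(cfg), simulate_storage(cfg))
  # and sensitive to the seed
  cfg2 <- synth_config(seed = 124, n_features = 50)
  expect_false(identical(simulate_untargeted(cfg)$features$mz,
                         simulate_untargeted(cfg2)$features$mz))
})

test_that("untargeted sample honours the configured class mix", {
  unt <- simulate_untargeted(synth_config(n_features = 300))
  frac <- table(unt$truth$class) / nrow(unt$truth)
  expect_lt(abs(frac[["CHO"]] - 0.80), 0.05)
  expect_lt(abs(frac[["other"]] - 0.16), 0.05)
  expect_true(all(unt$features$mz >= 70 & unt$features$mz <= 1000))
  expect_true(all(unt$features$area > 0))
  # planted members carry their series labels and CH2 indices
  planted <- unt$truth[!is.na(unt$truth$series), ]
  expect_equal(nrow(planted), 18)
  expect_equal(sum(planted$series == "dicarboxylic"), 6)
  expect_equal(sum(planted$series == "omega_hydroxy"), 12)
})

test_that("noiseless planting is exactly recoverable end to end", {
  cfg <- synth_config(n_features = 18, ppm_noise_sd = 0)
  unt <- simulate_untargeted(cfg)
  expect_equal(nrow(unt$features), 18)
  ann <- annotate_features(unt$features)
  expect_equal(ann$formula, unt$truth$formula)
  ser <- detect_homologues(ann)
  expect_equal(length(unique(ser$series_id)), 2)
  expect_setequal(unique(ser$kmd_key), c(0.105, 0.068))
})

test_that("every truth formula passes the annotator's chemical filters", {
  unt <- simulate_untargeted(synth_config(n_features = 200, seed = 9))
  for (fstr in unt$truth$formula) {
    f <- parse_formula(fstr)
    expect_gte(rdbe(f), 0)
    expect_equal(rdbe(f), round(rdbe(f)))
    expect_gte(element_count(f, "H"), 1)
    expect_lte(elemental_ratios(f)$h_c, 3)
  }
})

test_that("calibration truth propagates through the fitted statistics", {
  cfg <- synth_config(seed = 11, sigma_conc = 0)
  sim <- simulate_calibration(cfg)
  an <- sim$truth$analytes
  for (i in seq_len(nrow(an))) {
    curve <- fit_calibration(
      sim$calibration[sim$calibration$analyte == an$name[i], ])
    expect_equal(curve$slope, an$rf[i], tolerance = 1e-9)
    expect_equal(curve$sigma, 0, tolerance = 1e-9)
  }
  # spike truth recovers the configured recovery fractions
  sp <- sim$spikes[sim$spikes$analyte == "pinic acid", ]
  # noiseless spikes equal nominal x recovery, so recovery() is exact
  expect_equal(recovery(sp$measured, sp$nominal)$mean, 87,
               tolerance = 2)
})

test_that("storage generator applies the configured losses", {
  cfg <- synth_config(seed = 13)
  sto <- simulate_storage(cfg)
  # lossless cartridges for targeted analytes: ratios near 1
  tg <- sto$targeted[sto$targeted$mode == "spe_cartridge", ]
  tg$key <- tg$analyte
  cmp <- compare_storage(tg)
  expect_true(all(abs(cmp$ratio - 1) < 0.3))
  # syringaldehyde loses 85 % in glass vials
  gv <- sto$targeted[sto$targeted$mode == "glass_vial" &
                       sto$targeted$analyte == "syringaldehyde", ]
  gv$key <- gv$analyte
  r <- compare_storage(gv)
  expect_lt(abs(r$ratio - 0.15), 0.1)
  # zero loss everywhere means all ratios 1 (up to jitter)
  cfg0 <- synth_config(seed = 13, cartridge_loss_range = c(0, 0),
                       vial_loss_range = c(0, 0),
                       storage_jitter_sdlog = 0, dropout_prob = 0,
                       targeted_noise_rel = 0,
                       vial_losses = c(
                         "syringic acid" = 0, "vanillic acid" = 0,
                         "vanillin" = 0, "syringaldehyde" = 0,
                         "p-hydroxybenzoic acid" = 0, "pinic acid" = 0))
    sto0 <- simulate_storage(cfg0)
  cmp0 <- compare_storage(sto0$untargeted)
  expect_true(all(abs(cmp0$ratio - 1) < 1e-12))
})
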