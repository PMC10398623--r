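make_points <- function(rf, conc = c(0.5, 1, 2, 5, 10, 15),
                        is_area = 1e6, noise = 0) {
  ratio <- rf * conc + noise
  data.frame(concentration = conc, analyte_area = ratio * is_area,
             is_area = is_area)
}

test_that("calibration recovers exact response factors", {
  c1 <- fit_calibration(make_points(1.1))
  expect_equal(c1$slope, 1.1, tolerance = 1e-12)
  expect_equal(c1$r2, 1, tolerance = 1e-12)
  expect_equal(c1$sigma, 0, tolerance = 1e-9)
  expect_equal(fit_calibration(make_points(3.8))$slope, 3.8,
               tolerance = 1e-12)
})

test_that("calibration guards its preconditions", {
  pts <- make_points(1)
  expect_error(fit_calibration(pts[, c("concentration", "analyte_area")]),
               "is_area")
  bad <- pts; bad$is_area[2] <- 0
  expect_error(fit_calibration(bad), "internal standard")
  same <- make_points(1, conc = rep(5, 6))
  expect_error(fit_calibration(same), "distinct")
})

test_that("noisy calibration estimates RF within 2 standard errors", {
  set.seed(77)
  rf <- 2.2; sigma <- 0.1
  ests <- replicate(200, {
    pts <- make_points(rf, noise = rnorm(6, 0, sigma))
    fit_calibration(pts)$slope
  })
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - rf), 2 * se_mean)
})

test_that("LOD is 3.3 sigma over slope, converted through 20 uL", {
  curve <- structure(list(analyte = NA, slope = 0.01, intercept = 0,
                          r2 = 1, sigma = 0.03, n_points = 6),
                     class = "calibration_curve")
  l <- lod(curve)
  expect_equal(l$conc, 9.9, tolerance = 1e-12)
  expect_equal(l$pg, 198, tolerance = 1e-12)
  curve$sigma <- 0
  expect_equal(lod(curve)$pg, 0)
  curve$slope <- -1
  expect_error(lod(curve), "slope")
})

test_that("MDL is three blank standard deviations and scales linearly", {
  expect_equal(mdl(rep(0.004, 14)), 0)
  blanks <- c(0.001, 0.005, 0.009)  # sd 0.004
  expect_equal(mdl(blanks), 0.012, tolerance = 1e-12)
  expect_equal(mdl(blanks * 7), 7 * mdl(blanks), tolerance = 1e-12)
  expect_error(mdl(0.1), "at least 2")
  set.seed(12)
  b <- rnorm(14, 0.01, 0.001)
  expect_equal(mdl(b), 0.003, tolerance = 0.4)  # sampling error at n = 14
})

test_that("accuracy and precision follow the QC definitions", {
  ap <- accuracy_precision(c(0.9, 0.9, 0.9), 1)
  expect_equal(ap$accuracy, -10, tolerance = 1e-12)
  expect_equal(ap$precision, 0, tolerance = 1e-12)
  expect_equal(accuracy_precision(c(10.4, 10.4, 10.4), 10)$accuracy, 4,
               tolerance = 1e-12)
  expect_error(accuracy_precision(c(1, 1), 0), "non-zero")
  expect_error(accuracy_precision(1, 1), "replicates")
})

test_that("matrix effect compares response factors relative to UPW", {
  expect_equal(matrix_effect(1.0, 1.0), 0)
  expect_equal(matrix_effect(1.0, 0.91), 9, tolerance = 1e-12)
  expect_equal(matrix_effect(2, 2.2), -10, tolerance = 1e-12)
  expect_error(matrix_effect(0, 1), "positive")
  set.seed(21)
  for (a in runif(10, 0.5, 5)) expect_equal(matrix_effect(a, a), 0)
})

test_that("matrix effect of replicate identical-truth curves is null", {
  set.seed(31)
  rf <- 1.0; sigma <- 0.02
  effects <- replicate(30, {
    upw <- fit_calibration(make_points(rf, noise = rnorm(6, 0, sigma)))
    mat <- fit_calibration(make_points(rf, noise = rnorm(6, 0, sigma)))
    matrix_effect(upw$slope, mat$slope)
  })
  expect_gt(t.test(effects, mu = 0)$p.value, 0.05)
})

test_that("recovery aggregates per level and tests level independence", {
  r <- recovery(c(0.87, 0.87), c(1, 1))
  expect_equal(r$mean, 87, tolerance = 1e-12)
  expect_equal(recovery(c(1, 2), c(1, 2))$mean, 100)
  set.seed(41)
  nominal <- rep(c(0.03, 0.1, 1), each = 4)
  measured <- nominal * 0.75 * (1 + rnorm(12, 0, 0.08))
  r3 <- recovery(measured, nominal)
  expect_lt(abs(r3$mean - 75), 3 * r3$sd / sqrt(12) * 3)
  expect_gt(r3$p_level, 0.05)   # no level effect when truth is flat
  expect_equal(nrow(r3$per_level), 3)
  expect_error(recovery(1, 0), "non-zero")
})

test_that("quantification inverts the forward simulation exactly", {
  curve <- fit_calibration(make_points(2.2))
  true_conc <- c(0.15, 0.553, 3)
  is_area <- 1e6
  # forward: instrument sees recovery-attenuated analyte
  areas <- 2.2 * true_conc * 0.87 * is_area
  q <- quantify_sample(areas, rep(is_area, 3), curve,
                       recovery_pct = 87, mdl = 0.010)
  expect_equal(q$corrected_conc, true_conc, tolerance = 1e-9)
  expect_true(all(q$above_mdl))
  # a value below the MDL is reported but flagged
  q2 <- quantify_sample(2.2 * 0.005 * 0.87 * is_area, is_area, curve,
                        recovery_pct = 87, mdl = 0.010)
  expect_false(q2$above_mdl)
  expect_gt(q2$corrected_conc, 0)
})

test_that("responses below the intercept clamp to zero with a warning", {
  pts <- make_points(1.5)
  pts$analyte_area <- pts$analyte_area + 0.05 * pts$is_area  # intercept
  curve <- fit_calibration(pts)
  expect_warning(q <- quantify_sample(0.01 * 1e6, 1e6, curve),
                 "clamped")
  expect_equal(q$raw_conc, 0)
})

test_that("validation report assembles every statistic per analyte", {
  sim <- simulate_calibration(synth_config(seed = 7))
  rep <- validation_report(sim$calibration, sim$qc, sim$blanks,
                           sim$spikes, sim$matrix_calibration)
  an <- sim$truth$analytes
  expect_setequal(unique(rep$analyte), an$name)
  expect_equal(nrow(rep), nrow(an) * 2)  # two QC levels
  for (i in seq_len(nrow(an))) {
    row <- rep[rep$analyte == an$name[i], ][1, ]
    expect_lt(abs(row$rf - an$rf[i]) / an$rf[i], 0.05)
    expect_lt(abs(row$recovery_mean - an$recovery_pct[i]), 10)
    expect_gt(row$r2, 0.98)
  }
})
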