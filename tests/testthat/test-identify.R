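test_that("spectral similarity has the right fixed points", {
  s <- spectrum(c(100, 150, 200), c(100, 50, 10))
  expect_equal(spectral_similarity(s, s), 100, tolerance = 1e-9)
  disjoint <- spectrum(c(101, 151), c(100, 50))
  expect_equal(spectral_similarity(s, disjoint), 0)
  # hand-computed sqrt-cosine: vectors (10, sqrt(50)) vs (10, 0)
  a <- spectrum(c(100, 150), c(100, 50))
  b <- spectrum(100, 100)
  expect_equal(spectral_similarity(a, b), 100 * 10 / sqrt(150),
               tolerance = 1e-9)
  expect_equal(round(spectral_similarity(a, b), 1), 81.6)
})

test_that("similarity is symmetric and scale-invariant", {
  set.seed(9)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- spectrum(runif(n1, 50, 300), runif(n1, 1, 100))
    b <- spectrum(runif(n2, 50, 300), runif(n2, 1, 100))
    expect_equal(spectral_similarity(a, b), spectral_similarity(b, a),
                 tolerance = 1e-9)
    b2 <- spectrum(b$mz, b$intensity * 37.5)
    expect_equal(spectral_similarity(a, b), spectral_similarity(a, b2),
                 tolerance = 1e-9)
  }
})

test_that("spectrum construction and MSP round trip", {
  expect_error(spectrum(numeric(0), numeric(0)), "no peaks")
  expect_error(spectrum(100, -1), "negative")
  s <- normalize_spectrum(spectrum(c(100, 150), c(20, 80)))
  expect_equal(max(s$intensity), 100)
  specs <- list(
    x = spectrum(c(100.12345, 150.5), c(100, 50), precursor_mz = 200.1,
                 name = "x"),
    y = spectrum(90.5, 100, name = "y")
  )
  path <- tempfile(fileext = ".msp")
  write_msp(specs, path)
  back <- read_msp(path)
  expect_named(back, c("x", "y"))
  expect_equal(back$x$mz, specs$x$mz, tolerance = 1e-5)
  expect_equal(back$x$precursor_mz, 200.1, tolerance = 1e-4)
})

test_that("level assignment reproduces the worked suspect cases", {
  stds <- table2_standards()
  # succinic acid: RT 3.89 vs standard 3.88, library match 87.2 -> Level 1
  r <- assign_level("C4H6O4", rt = 3.89, n_candidates = 1,
                    standards = stds, library_score = 87.2)
  expect_equal(r$level, 1L)
  expect_equal(r$matched_standard, "succinic acid")
  expect_equal(r$delta_rt, 0.01, tolerance = 1e-9)
  # C6H10O4 at RT 8.19 vs 3-methylglutaric 6.71: isomer at Level 2
  r2 <- assign_level("C6H10O4", rt = 8.19, n_candidates = 1,
                     standards = stds, library_score = 87.5)
  expect_equal(r2$level, 2L)
  # unique formula, no standard, no library hit -> Level 4
  r4 <- assign_level("C8H12O4", rt = 7.51, n_candidates = 1,
                     standards = stds)
  expect_equal(r4$level, 4L)
  # no formula at all -> Level 5
  expect_equal(assign_level(NA, 5, 0)$level, 5L)
  # weak spectral match -> Level 3
  expect_equal(assign_level("C8H12O4", 7.51, 1, stds,
                            library_score = 60)$level, 3L)
  # several surviving formulas, no other evidence -> Level 3
  expect_equal(assign_level("C8H12O4", 7.51, 3)$level, 3L)
  expect_error(assign_level("C4H6O4", 1, 1, rt_tol = -1), "positive")
})

test_that("standard-spectrum evidence can raise an RT match to Level 1", {
  qs <- spectrum(c(73.03, 99.01, 117.02), c(100, 60, 30))
  stds <- data.frame(name = "succinic acid", formula = "C4H6O4",
                     rt = 3.88)
  stds$spectrum <- list(qs)
  r <- assign_level("C4H6O4", 3.89, 1, stds, query_spectrum = qs)
  expect_equal(r$level, 1L)
  expect_equal(r$match_score, 100, tolerance = 1e-9)
  # without any spectral evidence the RT match alone is Level 4 unless
  # the rt-only flag is set
  stds2 <- data.frame(name = "succinic acid", formula = "C4H6O4",
                      rt = 3.88)
  expect_equal(assign_level("C4H6O4", 3.89, 1, stds2)$level, 4L)
  expect_equal(assign_level("C4H6O4", 3.89, 1, stds2,
                            rt_only_level1 = TRUE)$level, 1L)
})

test_that("tightening the RT tolerance never improves the level", {
  stds <- table2_standards()
  tols <- c(0.2, 0.1, 0.05, 0.005)
  lv <- vapply(tols, function(tt) {
    assign_level("C4H6O4", 3.89, 1, stds, library_score = 87.2,
                 rt_tol = tt)$level
  }, integer(1))
  expect_true(all(diff(lv) >= 0))
})

test_that("identification is order-independent in the standards list", {
  stds <- table2_standards()
  feats <- annotate_features(table2_features())
  a <- identify_features(feats, stds)
  b <- identify_features(feats, stds[sample(nrow(stds)), ])
  expect_equal(a$level, b$level)
  expect_equal(a$matched_standard, b$matched_standard)
})

test_that("level census sums and handles empty input", {
  expect_equal(sum(level_census(c(1, 1, 2, 4, 5))), 5)
  expect_equal(level_census(integer(0)),
               c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L, `5` = 0L))
  expect_equal(level_census(rep(5, 3))[["5"]], 3L)
  expect_error(level_census(c(1, 7)), "1-5")
})
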