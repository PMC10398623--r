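test_that("Kendrick constants and reference mapping are exact", {
  b <- kendrick_basis()
  expect_equal(b$nominal, 14)
  expect_lt(abs(b$exact - 14.01565), 1e-5)
  expect_equal(kendrick_mass(b$exact), 14, tolerance = 1e-12)
  expect_equal(kendrick_mass_defect(b$exact), 0, tolerance = 1e-12)
})

test_that("Kendrick mass is CH2-additive", {
  km_succ <- kendrick_mass(monoisotopic_mass("C4H6O4"))
  expect_equal(km_succ, 117.89483, tolerance = 1e-5)
  km_glut <- kendrick_mass(monoisotopic_mass("C5H8O4"))
  expect_equal(km_glut, km_succ + 14, tolerance = 1e-9)
  expect_error(kendrick_mass(-1), "positive")
})

test_that("series keys reproduce the two homologue families", {
  # linear aliphatic dicarboxylic acids C2O4H2(CH2)n
  expect_equal(kmd_series_key(
    kendrick_mass_defect(monoisotopic_mass("C4H6O4"))), 0.105)
  # omega-hydroxy fatty acids CnH2nO3 (smallest member C2H4O3)
  expect_equal(kmd_series_key(
    kendrick_mass_defect(monoisotopic_mass("C2H4O3"))), 0.068)
})

test_that("KMD is invariant under CH2 addition, exactly", {
  ch2 <- parse_formula("CH2")
  set.seed(5)
  for (i in 1:20) {
    f <- random_formula()
    kmd0 <- kendrick_mass_defect(monoisotopic_mass(f))
    km0 <- kendrick_mass(monoisotopic_mass(f))
    g <- f
    for (k in 1:20) {
      g <- g + ch2
      km <- kendrick_mass(monoisotopic_mass(g))
      expect_equal(km - km0, 14 * k, tolerance = 1e-9)
      expect_equal(kendrick_mass_defect(monoisotopic_mass(g)), kmd0,
                   tolerance = 1e-9)
    }
  }
})

test_that("planted homologue series are detected with their keys", {
  diacids <- data.frame(
    id = paste0("d", 2:7),
    formula = sprintf("C%dH%dO4", 2 + 2:7, 2 + 2 * (2:7)),
    mz = NA_real_
  )
  s <- detect_homologues(diacids)
  expect_equal(length(unique(s$series_id)), 1)
  expect_equal(nrow(s), 6)
  expect_true(all(s$kmd_key == 0.105))
  expect_equal(sort(s$n_ch2), 0:5)
  expect_equal(s$base_formula[1], "C4H6O4")

  omega <- data.frame(
    id = paste0("w", 2:13),
    formula = sprintf("C%dH%dO3", 2:13, 2 * (2:13)),
    mz = NA_real_
  )
  s2 <- detect_homologues(omega)
  expect_equal(length(unique(s2$series_id)), 1)
  expect_equal(nrow(s2), 12)
  expect_true(all(s2$kmd_key == 0.068))
})

test_that("non-CH2 spacing and singletons yield no series", {
  two <- data.frame(id = c("a", "b"), mz = c(150.0, 163.5))
  expect_equal(nrow(detect_homologues(two)), 0)
  one <- data.frame(id = "a", mz = 150.0)
  expect_equal(nrow(detect_homologues(one)), 0)
})

test_that("series detection separates the two families and is stable", {
  both <- data.frame(
    id = c(paste0("d", 2:7), paste0("w", 2:13)),
    formula = c(sprintf("C%dH%dO4", 2 + 2:7, 2 + 2 * (2:7)),
                sprintf("C%dH%dO3", 2:13, 2 * (2:13))),
    mz = NA_real_
  )
  s <- detect_homologues(both)
  expect_equal(length(unique(s$series_id)), 2)
  expect_equal(anyDuplicated(s$id), 0)  # each member in at most one series
  expect_setequal(unique(s$kmd_key), c(0.105, 0.068))
  # idempotent: same input, same grouping
  expect_identical(s, detect_homologues(both))
})

test_that("Van Krevelen / Kroll classification follows the region rules", {
  succ <- classify_compound("C4H6O4")
  expect_equal(succ$os_c, 0.5)
  expect_equal(succ$vk_region, "other")   # O/C = 1 is not < 1
  expect_false(succ$kroll_band)           # OS_C = 0.5 boundary excluded
  expect_equal(classify_compound("C7H6O2")$vk_region, "aromatic")
  lev <- classify_compound("C5H8O3")
  expect_equal(lev$os_c, -0.4, tolerance = 1e-12)
  expect_true(lev$kroll_band)
  expect_equal(classify_compound("C10H16O4")$vk_region, "OOA")
  # O/C exactly 0.3 sits on the strict boundary and falls outside
  expect_equal(classify_compound("C10H16O3")$vk_region, "other")
  expect_error(classify_compound("H2O"), "carbon")
})

test_that("oxidation state responds to H2 and O as expected", {
  set.seed(3)
  for (i in 1:20) {
    C <- sample(3:15, 1); H <- 2 * sample(2:10, 1); O <- sample(1:8, 1)
    f0 <- as_molform(c(C = C, H = H, O = O))
    plus_h2 <- as_molform(c(C = C, H = H + 2, O = O))
    plus_o <- as_molform(c(C = C, H = H, O = O + 1))
    expect_lt(classify_compound(plus_h2)$os_c, classify_compound(f0)$os_c)
    expect_gt(classify_compound(plus_o)$os_c, classify_compound(f0)$os_c)
  }
})

test_that("diagram tables restrict the Kendrick panel to abundant CHO", {
  ann <- data.frame(
    id = c("a", "b", "c", "d"),
    mz = c(117.019, 130.051, 117.019, 145.051),
    rt = c(1, 2, 3, 4),
    area = c(1e8, 1e8, 1e6, 6e6),
    formula = c("C4H6O4", "C6H11NO2", NA, "C6H10O4"),
    class = c("CHO", "CHNO", "other", "CHO"),
    stringsAsFactors = FALSE
  )
  d <- diagram_tables(ann, kendrick_area_min = 5e6)
  expect_equal(nrow(d$mz_rt), 4)
  expect_equal(nrow(d$van_krevelen), 3)   # formula-less feature dropped
  expect_setequal(d$kendrick$id, c("a", "d"))  # CHO above area filter
  # empty after the area filter is fine
  d2 <- diagram_tables(ann, kendrick_area_min = 1e12)
  expect_equal(nrow(d2$kendrick), 0)
})
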