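test_that("CSV round-trip preserves values, including degenerate and large sets", {
  spectraPath <- withr::local_tempfile(fileext = ".csv")
  metaPath <- withr::local_tempfile(fileext = ".csv")

  s <- make_set(matrix(rnorm(15), 3, 5))
  writeSpectra(s, spectraPath, metaPath)
  r <- readSpectra(spectraPath, metaPath)
  expect_equal(spectraMatrix(r), spectraMatrix(s), tolerance = 1e-12)
  expect_equal(wavenumbers(r), wavenumbers(s))
  expect_equal(sampleMeta(r), sampleMeta(s))

  # empty set round-trips to empty
  e <- SpectraSet(matrix(numeric(), 0, 5), seq(6000, by = -8, length.out = 5),
                  data.frame(sample_id = character(),
                             concentration = numeric(),
                             replicate_group = character(),
                             role = character()))
  writeSpectra(e, spectraPath, metaPath)
  r <- readSpectra(spectraPath, metaPath)
  expect_equal(ncol(spectraMatrix(r)), 5L)
  expect_equal(nrow(spectraMatrix(r)), 0L)

  # 52-sample x 3-scan synthetic calibration design
  sim <- default_run()$sim
  writeSpectra(sim$spectra, spectraPath, metaPath)
  r <- readSpectra(spectraPath, metaPath)
  expect_equal(spectraMatrix(r), spectraMatrix(sim$spectra),
               tolerance = 1e-12)
})

test_that("malformed inputs are rejected with format/grid errors", {
  # metadata row count mismatch
  expect_error(
    SpectraSet(matrix(0, 3, 5), seq(6000, by = -8, length.out = 5),
               data.frame(sample_id = c("a", "b"), concentration = c(1, 2),
                          replicate_group = c("a", "b"), role = "unknown")),
    "format error")
  # non-uniform spacing (8 then 7 cm-1)
  expect_error(
    SpectraSet(matrix(0, 1, 3), c(10000, 9992, 9985),
               data.frame(sample_id = "a", concentration = 1,
                          replicate_group = "a", role = "unknown")),
    "grid error")
  # ascending grid
  expect_error(
    SpectraSet(matrix(0, 1, 3), c(4000, 4008, 4016),
               data.frame(sample_id = "a", concentration = 1,
                          replicate_group = "a", role = "unknown")),
    "grid error")
  # calibration role without concentration
  expect_error(
    SpectraSet(matrix(0, 1, 3), c(4016, 4008, 4000),
               data.frame(sample_id = "a", concentration = NA,
                          replicate_group = "a", role = "calibration")),
    "format error")
  # non-numeric absorbance in a CSV
  spectraPath <- withr::local_tempfile(fileext = ".csv")
  metaPath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,5000,4992", "a,1.0,oops"), spectraPath)
  writeLines(c("sample_id,concentration,replicate_group,role",
               "a,1,a,unknown"), metaPath)
  expect_error(readSpectra(spectraPath, metaPath), "format error")
})

test_that("region reduction keeps exactly the in-interval wavenumbers", {
  full <- make_set(matrix(rnorm(2 * 751), 2, 751), wn = nirGrid())
  red <- reduceRegions(full, defaultRegions())
  wn <- wavenumbers(red)
  expect_true(all((wn >= 5344 & wn <= 9612) | (wn >= 4068 & wn <= 4960)))
  # every grid point inside the intervals is retained
  expected <- sum((nirGrid() >= 5344 & nirGrid() <= 9612) |
                  (nirGrid() >= 4068 & nirGrid() <= 4960))
  expect_length(wn, expected)
  # idempotent
  expect_equal(spectraMatrix(reduceRegions(red, defaultRegions())),
               spectraMatrix(red))
  # full-range keep is the identity
  expect_equal(spectraMatrix(reduceRegions(full, rbind(c(4000, 10000)))),
               spectraMatrix(full))
  # no overlap with the grid
  expect_error(reduceRegions(full, rbind(c(1, 2))), "region error")
  # malformed intervals
  expect_error(reduceRegions(full, rbind(c(5000, 4900))), "region error")
  expect_error(reduceRegions(full, rbind(c(5000, 6000), c(5500, 7000))),
               "region error")
})

test_that("replicate averaging takes group means and validates metadata", {
  m <- rbind(c(0, 0, 0), c(2, 2, 2), c(5, 7, 9))
  s <- make_set(m, conc = c(10, 10, 20), group = c("g1", "g1", "g2"))
  a <- averageReplicates(s)
  expect_equal(spectraMatrix(a),
               rbind(c(1, 1, 1), c(5, 7, 9)), ignore_attr = TRUE)
  expect_equal(sampleMeta(a)$concentration, c(10, 20))
  expect_equal(sampleMeta(a)$sample_id, c("g1", "g2"))

  # averaging identical rows is the identity
  s2 <- make_set(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                 conc = rep(5, 3), group = rep("g", 3))
  expect_equal(spectraMatrix(averageReplicates(s2)),
               rbind(c(1, 2, 3)), ignore_attr = TRUE)

  # 156 scans (52 samples x 3) collapse to 52 rows
  sim <- default_run()$sim
  expect_equal(nrow(spectraMatrix(averageReplicates(sim$spectra))), 52L)

  # conflicting concentrations within a group
  bad <- make_set(matrix(0, 2, 3), conc = c(1, 2), group = c("g", "g"))
  expect_error(averageReplicates(bad), "metadata error")
})

test_that("averaging commutes with region reduction", {
  sim <- generateSpectraSet(studyDesign(
    concentrations = rep(c(0, 150), each = 2), seed = 3L))
  a <- reduceRegions(averageReplicates(sim$spectra), defaultRegions())
  b <- averageReplicates(reduceRegions(sim$spectra, defaultRegions()))
  expect_equal(spectraMatrix(a), spectraMatrix(b), tolerance = 1e-12)
})
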