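test_that("Gaussian component spectra evaluate as band sums", {
  grid <- nirGrid()
  one <- componentSpectrum("x", data.frame(center = 6000, width = 50,
                                           amplitude = 1), "analyte")
  spec <- gaussianSpectrum(one, grid)
  expect_equal(spec[grid == 6000], 1.0)
  expect_true(all(spec >= 0))
  none <- componentSpectrum("none", data.frame(center = numeric(),
                                               width = numeric(),
                                               amplitude = numeric()),
                            "analyte")
  expect_equal(gaussianSpectrum(none, grid), numeric(length(grid)))
  # the analyte preset concentrates its area near its band centers
  analyte <- componentPresets()$analyte
  spec <- gaussianSpectrum(analyte, grid)
  near <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(analyte$bands)))
    near <- near | abs(grid - analyte$bands$center[i]) <=
      3 * analyte$bands$width[i]
  expect_gte(sum(spec[near]) / sum(spec), 0.99)
})

test_that("generation is deterministic in the seed", {
  d <- studyDesign(concentrations = rep(c(0, 150), each = 2), seed = 71L)
  a <- generateSpectraSet(d)
  b <- generateSpectraSet(d)
  expect_identical(spectraMatrix(a$spectra), spectraMatrix(b$spectra))
  expect_identical(a$truth, b$truth)
  d2 <- studyDesign(concentrations = rep(c(0, 150), each = 2), seed = 72L)
  c2 <- generateSpectraSet(d2)
  expect_gt(max(abs(spectraMatrix(a$spectra) - spectraMatrix(c2$spectra))), 0)
})

test_that("a noise-free blank is background plus residual water only", {
  d <- studyDesign(concentrations = 0, scansPerSample = 1L, seed = 73L)
  out <- generateSpectraSet(d, noise = zeroNoiseModel())
  grid <- nirGrid()
  presets <- componentPresets()
  expected <- gaussianSpectrum(presets$sorbent, grid) +
    out$truth$water_amplitude[1] * gaussianSpectrum(presets$water, grid)
  expect_equal(drop(spectraMatrix(out$spectra)), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  # the water band is present even with zero analyte
  waterBand <- grid >= 4960 & grid <= 5344
  expect_gt(min(drop(spectraMatrix(out$spectra))[waterBand] -
                gaussianSpectrum(presets$sorbent, grid)[waterBand]), 0)
})

test_that("the noise-free analyte signal is linear in concentration", {
  mk <- function(conc) generateSpectraSet(
    studyDesign(concentrations = conc, scansPerSample = 1L, seed = 74L),
    noise = zeroNoiseModel())
  blank <- spectraMatrix(mk(0)$spectra)
  s1 <- spectraMatrix(mk(120)$spectra) - blank
  s2 <- spectraMatrix(mk(240)$spectra) - blank
  expect_equal(s2, 2 * s1, tolerance = 1e-10)
})

test_that("the standard design yields 52 samples x 3 scans", {
  sim <- default_run()$sim
  expect_equal(nrow(spectraMatrix(sim$spectra)), 156L)
  expect_equal(length(unique(sim$truth$replicate_group)), 52L)
  expect_equal(sort(unique(sim$truth$concentration)), seq(0, 300, by = 25))
  expect_true(all(is.finite(spectraMatrix(sim$spectra))))
  # adsorbed amount follows the extraction model
  expect_equal(sim$truth$adsorbed_mg_g,
               sim$truth$concentration * 0.974 * 0.004 / 0.1)
})

test_that("an uncalibrated extraction pH is rejected", {
  expect_error(studyDesign(ph = 5), "parameter error")
  expect_equal(adsorptionFraction(3.5), 0.974)
  expect_equal(adsorptionFraction(6), 0.303)
  expect_equal(adsorptionFraction(8), 0.359)
})

test_that("spectral ends are noisier than the retained interior", {
  d <- studyDesign(concentrations = rep(0, 10), scansPerSample = 3L,
                   seed = 75L)
  out <- generateSpectraSet(d)
  m <- spectraMatrix(out$spectra)
  grid <- nirGrid()
  colSd <- apply(m, 2, sd)
  edge <- grid < 4068 | grid > 9612
  expect_gt(mean(colSd[edge]), mean(colSd[!edge]))
})

test_that("the validation suite has the designed structure", {
  suite <- cached("valsuite", generateValidationSuite(seed = 76L))
  expect_equal(nrow(spectraMatrix(suite$repeatability$spectra)), 30L)
  expect_equal(length(unique(suite$repeatability$truth$replicate_group)), 10L)
  expect_named(suite$selectivity,
               c("control", "ascorbic", "tyrosine", "glucose"))
  expect_equal(suite$nominal, 150)
  # only the glucose condition carries spectral contamination
  expect_true(all(suite$selectivity$ascorbic$truth$contamination_amplitude == 0))
  expect_true(all(suite$selectivity$glucose$truth$contamination_amplitude > 0))
})

test_that("glucose contamination biases recovery and inflates its spread", {
  model <- default_run()$model
  stats_for <- function(seed) {
    suite <- generateValidationSuite(seed = seed)
    one <- function(set) {
      avg <- averageReplicates(applyPlan(set$spectra,
                                         preprocessPlan("reference")))
      predict(model, avg)
    }
    ctrl <- one(suite$selectivity$control)
    glu <- one(suite$selectivity$glucose)
    asc <- one(suite$selectivity$ascorbic)
    c(biasCtrl = abs(mean(ctrl) - 150), biasGlu = abs(mean(glu) - 150),
      sdCtrl = sd(ctrl), sdGlu = sd(glu), biasAsc = abs(mean(asc) - 150))
  }
  res <- vapply(101:110, stats_for, numeric(5))
  # sign test across 10 seeds: glucose is worse than the control
  expect_gte(sum(res["sdGlu", ] > res["sdCtrl", ]), 8)
  expect_gte(sum(res["biasGlu", ] > res["biasCtrl", ]), 8)
  # an interferent with no mechanism behaves like the control on average
  expect_lt(abs(mean(res["biasAsc", ]) - mean(res["biasCtrl", ])),
            2 * sd(res["biasCtrl", ]) + 2)
})
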