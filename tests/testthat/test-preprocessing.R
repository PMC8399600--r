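test_that("SNV centers and scales every spectrum (n-1 denominator)", {
  expect_equal(spectraMatrix(snv(make_set(rbind(c(1, 2, 3))))),
               rbind(c(-1, 0, 1)), ignore_attr = TRUE)
  # a row that is already mean 0, sd 1 is a fixed point
  row <- c(-1, 0, 1)
  expect_equal(spectraMatrix(snv(make_set(rbind(row)))), rbind(row),
               ignore_attr = TRUE)
  # postconditions on every row of a random set
  set.seed(5)
  out <- spectraMatrix(snv(make_set(matrix(rnorm(200), 10, 20))))
  expect_equal(unname(rowMeans(out)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 10), tolerance = 1e-12)
  # constant spectrum
  expect_error(snv(make_set(rbind(c(5, 5, 5)))), "degenerate-spectrum")
})

test_that("MSC removes affine scatter against the reference", {
  set.seed(6)
  ref <- rnorm(20)
  # rows that are exact affine transforms of the reference collapse onto it
  m <- rbind(2 * ref + 3, 0.5 * ref - 1, ref)
  out <- spectraMatrix(msc(make_set(m), reference = ref))
  for (i in 1:3) expect_equal(out[i, ], ref, tolerance = 1e-10,
                              ignore_attr = TRUE)
  # after correction each row regresses on the reference with slope 1,
  # intercept 0
  m2 <- matrix(rnorm(100), 5, 20)
  out2 <- spectraMatrix(msc(make_set(m2)))
  refMean <- colMeans(m2)
  for (i in 1:5) {
    fit <- lm(out2[i, ] ~ refMean)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-8)
  }
  expect_error(msc(make_set(m), reference = rep(2, 20)),
               "degenerate-reference")
})

test_that("detrending removes polynomials of the configured degree", {
  idx <- 1:30
  line <- 2 * idx + 7
  expect_equal(spectraMatrix(detrendSpectra(make_set(rbind(line)), 1L)),
               rbind(rep(0, 30)), tolerance = 1e-10, ignore_attr = TRUE)
  quad <- 0.3 * idx^2 - idx + 2
  expect_equal(spectraMatrix(detrendSpectra(make_set(rbind(quad)), 2L)),
               rbind(rep(0, 30)), tolerance = 1e-8, ignore_attr = TRUE)
  # degree 0 is mean removal
  set.seed(7)
  r <- rnorm(30)
  expect_equal(spectraMatrix(detrendSpectra(make_set(rbind(r)), 0L)),
               rbind(r - mean(r)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(detrendSpectra(make_set(rbind(r)), 3L), "parameter error")
})

test_that("Savitzky-Golay filtering matches its defining local fits", {
  # polyorder 0 = centered moving average
  out <- spectraMatrix(sgFilter(make_set(rbind(c(0, 3, 0, 3, 0))),
                                window = 3L, polyorder = 0L))
  expect_equal(unname(out[1, 3]), 2.0)
  expect_equal(unname(out[1, 2]), 1.0)
  # constant invariance at the packaged smoothing settings
  s <- make_set(matrix(4.2, 1, 25))
  expect_equal(spectraMatrix(sgFilter(s, 19L, 0L)),
               matrix(4.2, 1, 25), tolerance = 1e-12, ignore_attr = TRUE)
  # smoothing with polyorder >= polynomial degree reproduces the row,
  # including the fit-based edges
  wn <- seq(6000, by = -8, length.out = 25)
  quad <- 1e-4 * (wn - 5900)^2
  sq <- make_set(rbind(quad), wn = wn)
  expect_equal(spectraMatrix(sgFilter(sq, 7L, 2L)), rbind(quad),
               tolerance = 1e-8, ignore_attr = TRUE)
  # first derivative of a line equals its slope per cm-1 everywhere
  lin <- make_set(rbind(0.01 * wn + 3), wn = wn)
  d1 <- spectraMatrix(sgFilter(lin, 5L, 1L, derivorder = 1L))
  expect_equal(d1, matrix(0.01, 1, 25), tolerance = 1e-10,
               ignore_attr = TRUE)
  # parameter validation
  expect_error(sgFilter(s, 4L, 0L), "parameter error")
  expect_error(sgFilter(s, 31L, 0L), "parameter error")
  expect_error(sgFilter(s, 5L, 0L, derivorder = 1L), "parameter error")
})

test_that("pretreatment plans compose and the reference preset ends in SNV", {
  sim <- generateSpectraSet(studyDesign(
    concentrations = rep(c(0, 100, 300), each = 2), seed = 9L))
  out <- applyPlan(sim$spectra, preprocessPlan("reference"))
  m <- spectraMatrix(out)
  expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-10)
  expect_equal(unname(apply(m, 1, sd)), rep(1, nrow(m)), tolerance = 1e-10)
  # empty plan is the identity
  expect_equal(spectraMatrix(applyPlan(sim$spectra, preprocessPlan(steps = list()))),
               spectraMatrix(sim$spectra))
  # the chain is not idempotent: a second application changes the rows
  out2 <- applyPlan(out, preprocessPlan("reference"))
  expect_gt(max(abs(spectraMatrix(out2) - m)), 1e-6)
})

test_that("all operators are row-independent (commute with permutation)", {
  set.seed(8)
  s <- make_set(matrix(rnorm(8 * 30), 8, 30))
  perm <- sample(8)
  permute <- function(x) {
    m <- spectraMatrix(x)[perm, , drop = FALSE]
    meta <- sampleMeta(x)[perm, ]
    SpectraSet(m, wavenumbers(x), meta)
  }
  ref <- colMeans(spectraMatrix(s))  # fixed reference so MSC is row-local
  ops <- list(
    snv = function(x) snv(x),
    msc = function(x) msc(x, reference = ref),
    detrend = function(x) detrendSpectra(x, 1L),
    sg = function(x) sgFilter(x, 5L, 2L)
  )
  for (nm in names(ops)) {
    expect_equal(spectraMatrix(ops[[nm]](permute(s))),
                 spectraMatrix(permute(ops[[nm]](s))),
                 tolerance = 1e-12, ignore_attr = TRUE, label = nm)
  }
})

test_that("plans serialize through the YAML config representation", {
  plan <- preprocessPlan("reference")
  cfg <- defaultConfig()
  cfg$plan <- plan
  path <- withr::local_tempfile(fileext = ".yaml")
  writePipelineConfig(cfg, path)
  back <- readPipelineConfig(path)
  expect_equal(length(back$plan), length(plan))
  expect_equal(vapply(back$plan, `[[`, "", "kind"),
               vapply(plan, `[[`, "", "kind"))
  expect_equal(back$plan[[2]]$regions, unname(plan[[2]]$regions),
               ignore_attr = TRUE)
})
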