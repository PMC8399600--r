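#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpectraSet: a set of NIR spectra with sample metadata
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of near-infrared diffuse-reflectance spectra on a common wavenumber
#' grid.  Rows are wavenumbers (stored in descending instrument order, cm-1),
#' columns are individual spectra (scans).  The single assay `"absorbance"`
#' holds the absorbance matrix; `rowData` carries the wavenumber grid and
#' `colData` the per-sample metadata: `sample_id`, `concentration`
#' (mg L-1 gallic acid equivalents, `NA` when unknown), `replicate_group`
#' (scans of the same physical sample share a group and are averaged
#' together), and `role` (one of `"calibration"`, `"validation"`, `"blank"`,
#' `"unknown"`).
#'
#' Validity requires a strictly descending, uniformly spaced grid inside
#' 4000--10000 cm-1 (relative spacing tolerance 1e-9), all-finite
#' absorbances, non-negative concentrations where present, and a present
#' concentration for every `role == "calibration"` sample.
#'
#' @seealso [readSpectra()], [writeSpectra()], [reduceRegions()],
#'   [averageReplicates()], [spectraMatrix()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' PLSModel: a fitted NIPALS PLS1 regression model
#'
#' Holds everything needed to predict from new spectra and to derive figures
#' of merit: the centering vectors, per-factor weights `W` (p x A), scores
#' `T` (n x A), X-loadings `P` (p x A), y-loadings `q` (length A), the
#' assembled regression coefficient vector `b = W (P'W)^-1 q` (length p) and
#' the number of latent factors `A`.  `wavenumbers` records the grid the
#' model was trained on (may be `NA` for bare-matrix fits).
#'
#' @slot xMean numeric, column means of the training matrix (length p).
#' @slot yMean numeric(1), mean of the training response.
#' @slot weights p x A weight matrix (unit-norm columns).
#' @slot scores n x A score matrix (mutually orthogonal columns).
#' @slot xLoadings p x A X-loading matrix.
#' @slot yLoadings numeric(A), y-loadings.
#' @slot coefficients numeric(p), regression coefficient vector.
#' @slot nFactors integer(1), number of latent factors.
#' @slot wavenumbers numeric, training wavenumber grid or `NA`.
#' @seealso [fitNipals()], [predict,PLSModel-method], [crossValidate()]
#' @export
setClass("PLSModel",
  representation(
    xMean = "numeric",
    yMean = "numeric",
    weights = "matrix",
    scores = "matrix",
    xLoadings = "matrix",
    yLoadings = "numeric",
    coefficients = "numeric",
    nFactors = "integer",
    wavenumbers = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  p <- length(object@xMean)
  A <- object@nFactors
  msg <- character()
  if (length(A) != 1L || A < 1L)
    msg <- c(msg, "nFactors must be a single positive integer")
  if (!all(dim(object@weights) == c(p, A)))
    msg <- c(msg, "weights must be p x A")
  if (ncol(object@scores) != A)
    msg <- c(msg, "scores must have A columns")
  if (!all(dim(object@xLoadings) == c(p, A)))
    msg <- c(msg, "xLoadings must be p x A")
  if (length(object@yLoadings) != A)
    msg <- c(msg, "yLoadings must have length A")
  if (length(object@coefficients) != p)
    msg <- c(msg, "coefficients must have length p")
  if (length(msg)) msg else TRUE
})

#' CalibrationMetrics: per-factor calibration and cross-validation errors
#'
#' Per candidate factor count a = 1..A_max: root-mean-square error of
#' calibration RMSEC(a) and of cross-validation RMSEV(a), and coefficients of
#' determination R2cal(a) (on fitted values) and R2val(a) (on left-out
#' predictions), both computed as 1 - SS_res/SS_tot about the overall mean.
#' `chosenFactors` is the selected factor count (see [crossValidate()]).
#'
#' @slot table data.frame with columns `factors`, `rmsec`, `r2cal`,
#'   `rmsev`, `r2val`.
#' @slot chosenFactors integer(1).
#' @seealso [crossValidate()], [metricsTable()], [chosenFactors()]
#' @export
setClass("CalibrationMetrics",
  representation(table = "data.frame", chosenFactors = "integer")
)

setValidity("CalibrationMetrics", function(object) {
  need <- c("factors", "rmsec", "r2cal", "rmsev", "r2val")
  msg <- character()
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must have columns factors, rmsec, r2cal, rmsev, r2val")
  else {
    if (any(!is.finite(as.matrix(object@table[need]))))
      msg <- c(msg, "all metric values must be finite")
    if (is.unsorted(rev(object@table$rmsec) - 1e-9 * max(object@table$rmsec)))
      msg <- c(msg)  # monotonicity asserted in tests, not hard validity
  }
  if (length(object@chosenFactors) != 1L ||
      !(object@chosenFactors %in% object@table$factors))
    msg <- c(msg, "chosenFactors must be one of the tabulated factor counts")
  if (length(msg)) msg else TRUE
})

#' FiguresOfMerit: multivariate sensitivity, leverages and LOD/LOQ
#'
#' Figures of merit for a multivariate calibration: sensitivity `SEN` (the
#' inverse Euclidean norm of the regression coefficient vector, signal units
#' per mg L-1), instrumental signal variance `var(x)`, variance of the
#' calibration concentrations `var(y_cal)`, minimal and maximal background
#' leverages `h0`, and the resulting interval-valued limits of detection and
#' quantification (mg L-1), with
#' `LOD = 3.3 * sqrt(SEN^-2 var(x) + h0 SEN^-2 var(x) + h0 var(y_cal))` and
#' `LOQ = 3 * LOD`.  `workingRange` is `[LOQ_min, upper calibration bound]`.
#'
#' @slot sen numeric(1), sensitivity (> 0).
#' @slot varX numeric(1), instrumental signal variance.
#' @slot varYcal numeric(1), variance of calibration concentrations.
#' @slot h0Min,h0Max numeric(1), background leverage extremes.
#' @slot lodMin,lodMax,loqMin,loqMax numeric(1), detection and
#'   quantification limits in mg L-1.
#' @slot workingRange numeric(2), `[LOQ_min, max calibration concentration]`.
#' @seealso [computeFom()], [sensitivity()], [backgroundLeverages()],
#'   [lodValue()], [loqValue()]
#' @export
setClass("FiguresOfMerit",
  representation(
    sen = "numeric", varX = "numeric", varYcal = "numeric",
    h0Min = "numeric", h0Max = "numeric",
    lodMin = "numeric", lodMax = "numeric",
    loqMin = "numeric", loqMax = "numeric",
    workingRange = "numeric"
  )
)

setValidity("FiguresOfMerit", function(object) {
  msg <- character()
  ok1 <- function(x) length(x) == 1L && is.finite(x)
  if (!ok1(object@sen) || object@sen <= 0)
    msg <- c(msg, "sen must be a single positive finite number")
  for (nm in c("varX", "varYcal", "h0Min", "h0Max",
               "lodMin", "lodMax", "loqMin", "loqMax"))
    if (!ok1(slot(object, nm)) || slot(object, nm) < 0)
      msg <- c(msg, paste(nm, "must be a single non-negative finite number"))
  if (ok1(object@h0Min) && ok1(object@h0Max) && object@h0Min > object@h0Max)
    msg <- c(msg, "h0Min must not exceed h0Max")
  if (ok1(object@lodMin) && ok1(object@lodMax) &&
      object@lodMin > object@lodMax + 1e-12)
    msg <- c(msg, "lodMin must not exceed lodMax")
  if (length(object@workingRange) != 2L)
    msg <- c(msg, "workingRange must have length 2")
  if (length(msg)) msg else TRUE
})
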