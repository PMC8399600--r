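## Multivariate figures of merit: sensitivity, background leverages and the
## interval-valued limits of detection / quantification.

#' Multivariate sensitivity
#'
#' `SEN = 1 / ||b||_2`, the inverse Euclidean length of the regression
#' coefficient vector, in signal units per mg L-1.
#'
#' @param model a [PLSModel-class].
#' @return Positive scalar sensitivity.
#' @export
sensitivity <- function(model) {
  nb <- sqrt(sum(model@coefficients^2))
  if (nb == 0) stop("degenerate-model error: zero coefficient vector")
  1 / nb
}

#' Background leverages of the calibration samples
#'
#' For each calibration sample the analyte contribution is removed from its
#' score vector: `t0_n = t_n - y_cen,n * s`, where `s` is the least-squares
#' regression of each score column on the centered calibration
#' concentrations.  The background leverage is the squared length of the
#' residual score in the normalized score space,
#' `h0_n = sum_a t0_na^2 / sum_m t_ma^2`.  Its minimum and maximum over the
#' calibration set enter the LOD interval.
#'
#' @param model a [PLSModel-class] fitted on the calibration set.
#' @param yCal calibration concentrations, one per training sample.
#' @return Numeric vector of leverages, one per calibration sample.
#' @export
backgroundLeverages <- function(model, yCal) {
  Tm <- model@scores
  if (nrow(Tm) < 2L)
    stop("design error: background leverages require >= 2 calibration samples")
  if (length(yCal) != nrow(Tm))
    stop("shape error: yCal length must match the number of training samples")
  yc <- yCal - mean(yCal)
  ssy <- sum(yc^2)
  s <- if (ssy > 0) drop(crossprod(Tm, yc)) / ssy else numeric(ncol(Tm))
  T0 <- Tm - outer(yc, s)
  norms <- colSums(Tm^2)
  drop(T0^2 %*% (1 / norms))
}

#' Multivariate limit of detection
#'
#' `LOD = 3.3 * sqrt(SEN^-2 var(x) + h0 SEN^-2 var(x) + h0 var(y_cal))`,
#' combining the instrumental signal variance propagated through the model
#' sensitivity with the calibration-concentration variance weighted by the
#' background leverage.  `LOD_min`/`LOD_max` use `h0_min`/`h0_max`.
#'
#' @param sen sensitivity (> 0).
#' @param varX instrumental signal variance (>= 0).
#' @param h0 background leverage (>= 0).
#' @param varYcal variance of calibration concentrations (>= 0).
#' @return LOD in mg L-1.
#' @export
lodValue <- function(sen, varX, h0, varYcal) {
  if (sen <= 0) stop("parameter error: sensitivity must be positive")
  if (varX < 0 || varYcal < 0 || h0 < 0)
    stop("parameter error: variances and leverage must be non-negative")
  3.3 * sqrt(varX / sen^2 + h0 * varX / sen^2 + h0 * varYcal)
}

#' Limit of quantification
#'
#' `LOQ = 3 * LOD`.
#'
#' @param lod LOD value (>= 0).
#' @return LOQ in the same units.
#' @export
loqValue <- function(lod) 3 * lod

#' Assemble figures of merit for a fitted calibration
#'
#' Computes the sensitivity, the sample variance of the calibration
#' concentrations, the background-leverage extremes and the resulting
#' LOD/LOQ interval, plus the working range
#' `[LOQ_min, max calibration concentration]`.
#'
#' The instrumental signal variance `var(x)` defaults to the mean squared
#' X-residual after reconstruction from the model's factors, averaged over
#' the calibration spectra; a user-supplied estimate (for example the
#' variance of blank replicate spectra) can be passed through `varX`.
#'
#' @param model a [PLSModel-class] fitted on `calibration`.
#' @param calibration the pretreated, replicate-averaged
#'   [SpectraSet-class] the model was fitted on (calibration-role samples),
#'   or a numeric vector of calibration concentrations when `varX` is
#'   supplied.
#' @param varX optional externally estimated signal variance.
#' @param ... unused.
#' @return A [FiguresOfMerit-class].
#' @rdname computeFom
#' @export
setMethod("computeFom", "PLSModel", function(model, calibration,
                                             varX = NULL, ...) {
  if (methods::is(calibration, "SpectraSet")) {
    meta <- sampleMeta(calibration)
    sel <- meta$role == "calibration"
    if (!any(sel)) sel <- rep(TRUE, nrow(meta))
    y <- meta$concentration[sel]
    X <- spectraMatrix(calibration)[sel, , drop = FALSE]
  } else {
    y <- as.numeric(calibration)
    X <- NULL
    if (is.null(varX))
      stop("parameter error: varX is required without calibration spectra")
  }
  if (length(y) != nrow(model@scores))
    stop("shape error: calibration size differs from the fitted model")
  if (is.null(varX)) {
    Xc <- sweep(X, 2L, model@xMean)
    res <- Xc - tcrossprod(model@scores, model@xLoadings)
    varX <- mean(res^2)
  }
  sen <- sensitivity(model)
  varY <- stats::var(y)
  h0 <- backgroundLeverages(model, y)
  lodMin <- lodValue(sen, varX, min(h0), varY)
  lodMax <- lodValue(sen, varX, max(h0), varY)
  methods::new("FiguresOfMerit",
    sen = sen, varX = varX, varYcal = varY,
    h0Min = min(h0), h0Max = max(h0),
    lodMin = lodMin, lodMax = lodMax,
    loqMin = loqValue(lodMin), loqMax = loqValue(lodMax),
    workingRange = c(loqValue(lodMin), max(y)))
})

#' @rdname computeFom
#' @export
setMethod("workingRange", "FiguresOfMerit", function(x) x@workingRange)

#' Figures of merit as a one-row data.frame
#'
#' Column names match the report CSV; values are unrounded.
#' @param x a [FiguresOfMerit-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "FiguresOfMerit", function(x, ...) {
  data.frame(sen = x@sen, var_x = x@varX, var_ycal = x@varYcal,
             h0_min = x@h0Min, h0_max = x@h0Max,
             lod_min = x@lodMin, lod_max = x@lodMax,
             loq_min = x@loqMin, loq_max = x@loqMax,
             working_range_low = x@workingRange[1L],
             working_range_high = x@workingRange[2L])
})

setMethod("show", "FiguresOfMerit", function(object) {
  cat("FiguresOfMerit\n")
  cat(sprintf("  SEN %.4g, var(x) %.4g, var(y_cal) %.4g\n",
              object@sen, object@varX, object@varYcal))
  cat(sprintf("  h0 [%.4g, %.4g]\n", object@h0Min, object@h0Max))
  cat(sprintf("  LOD %.1f to %.1f mg L-1; LOQ %.1f to %.1f mg L-1\n",
              object@lodMin, object@lodMax, object@loqMin, object@loqMax))
  cat(sprintf("  working range %.1f to %.1f mg L-1\n",
              object@workingRange[1L], object@workingRange[2L]))
})
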