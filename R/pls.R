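## NIPALS PLS1 regression, prediction, cross-validation and serialization.
##
## The fitting algorithm is the classical single-response NIPALS: per
## factor, w = X'y / ||X'y||, t = Xw, p = X't / t't, q = y't / t't, then X
## and y are deflated.  The coefficient vector is assembled as
## b = W (P'W)^-1 q, so that yhat = y_mean + (X - x_mean) b.

#' Fit a PLS1 model by NIPALS
#'
#' @param X numeric matrix, n samples x p variables (not pre-centered; the
#'   function mean-centers internally, no variance scaling).
#' @param y numeric response of length n.
#' @param maxFactors number of latent factors A, at most `min(n - 1, p)`.
#'   When the data are numerically exhausted earlier (noiseless low-rank
#'   inputs) the model truncates to the supported factor count.
#' @param tol convergence tolerance on the change of the weight vector (the
#'   single-response algorithm converges in one pass; the iteration guard is
#'   retained for a future multi-response extension).
#' @param maxIter iteration cap per factor.
#' @param wavenumbers optional grid annotation stored with the model.
#' @return A [PLSModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(80), 8, 10)
#' y <- X %*% rnorm(10)
#' m <- fitNipals(X, y, maxFactors = 3)
#' range(predict(m, X) - y)
#' @export
fitNipals <- function(X, y, maxFactors, tol = 1e-10, maxIter = 500L,
                      wavenumbers = NA_real_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || p < 1L)
    stop("shape error: need at least 2 samples and 1 variable")
  if (length(y) != n)
    stop("shape error: length(y) must equal nrow(X)")
  if (maxFactors < 1L || maxFactors > min(n - 1L, p))
    stop("parameter error: maxFactors must lie in [1, min(n - 1, p)]")
  if (stats::var(y) == 0)
    stop("degenerate-target error: response has zero variance")
  A <- as.integer(maxFactors)
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2L, xMean)
  yc <- y - yMean
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  scale0 <- sqrt(sum(Xc^2)) + sqrt(sum(yc^2))
  aDone <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * scale0^2 + 1e-300) {
      ## X or y deflated to numerical zero: the data support fewer factors
      if (a == 1L) stop("degenerate-model error: zero weight vector")
      break
    }
    w <- w / nw
    for (iter in seq_len(maxIter)) {
      tvec <- drop(Xc %*% w)
      wNew <- drop(crossprod(Xc, yc))
      wNew <- wNew / sqrt(sum(wNew^2))
      if (sqrt(sum((wNew - w)^2)) < tol) { w <- wNew; break }
      w <- wNew
      if (iter == maxIter)
        stop("convergence error: NIPALS did not converge at factor ", a)
    }
    tvec <- drop(Xc %*% w)
    tt <- sum(tvec^2)
    if (tt <= (1e-14 * scale0)^2) {
      if (a == 1L) stop("degenerate-model error: zero score vector")
      break
    }
    pvec <- drop(crossprod(Xc, tvec)) / tt
    qa <- sum(yc * tvec) / tt
    Xc <- Xc - tcrossprod(tvec, pvec)
    yc <- yc - qa * tvec
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; q[a] <- qa
    aDone <- a
  }
  A <- aDone
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  b <- drop(W %*% solve(crossprod(P, W), q))
  methods::new("PLSModel",
    xMean = xMean, yMean = yMean, weights = W, scores = Tm,
    xLoadings = P, yLoadings = q, coefficients = b, nFactors = A,
    wavenumbers = as.numeric(wavenumbers))
}

#' Fit a calibration model from a SpectraSet
#'
#' Convenience wrapper around [fitNipals()] using the absorbance matrix and
#' the metadata concentrations of (by default) the `role == "calibration"`
#' samples; the wavenumber grid is stored with the model.
#'
#' @param x a pretreated, replicate-averaged [SpectraSet-class].
#' @param maxFactors number of latent factors.
#' @param role metadata role to select (default `"calibration"`).
#' @param ... passed to [fitNipals()].
#' @return A [PLSModel-class].
#' @export
fitCalibration <- function(x, maxFactors, role = "calibration", ...) {
  meta <- sampleMeta(x)
  sel <- meta$role == role
  if (!any(sel)) stop("design error: no samples with role '", role, "'")
  fitNipals(spectraMatrix(x)[sel, , drop = FALSE],
            meta$concentration[sel], maxFactors,
            wavenumbers = wavenumbers(x), ...)
}

#' Predict concentrations from a fitted PLS model
#'
#' `yhat = y_mean + (X_new - x_mean) b`.
#'
#' @param object a [PLSModel-class].
#' @param newdata numeric matrix (samples x variables) or a
#'   [SpectraSet-class] whose grid matches the training grid.
#' @return Numeric vector of predictions (mg L-1 GAE).
#' @aliases predict,PLSModel-method
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  if (methods::is(newdata, "SpectraSet")) {
    if (!anyNA(object@wavenumbers) &&
        (length(object@wavenumbers) != length(wavenumbers(newdata)) ||
         any(abs(object@wavenumbers - wavenumbers(newdata)) > 1e-9)))
      stop("shape error: wavenumber grid differs from the training grid")
    newdata <- spectraMatrix(newdata)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("shape error: ", ncol(newdata), " variables but model was trained on ",
         length(object@xMean))
  drop(object@yMean + sweep(newdata, 2L, object@xMean) %*% object@coefficients)
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", length(object@xMean), "variables,",
      object@nFactors, "latent factors\n")
  cat(sprintf("  y mean %.4g; |b| = %.4g\n", object@yMean,
              sqrt(sum(object@coefficients^2))))
})

#' Model coefficients
#' @param object a [PLSModel-class].
#' @param ... ignored.
#' @return The regression coefficient vector `b`.
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)

## predictions for all factor counts 1..A in a single deflation pass
.pls_predict_path <- function(model, xnew) {
  xc <- as.numeric(xnew) - model@xMean
  A <- model@nFactors
  preds <- numeric(A)
  acc <- model@yMean
  for (a in seq_len(A)) {
    tnew <- sum(xc * model@weights[, a])
    acc <- acc + model@yLoadings[a] * tnew
    xc <- xc - tnew * model@xLoadings[, a]
    preds[a] <- acc
  }
  preds
}

.rmse <- function(e) sqrt(mean(e^2))

#' Cross-validated calibration metrics
#'
#' Fits models with 1..`maxFactors` latent factors and evaluates them by
#' cross-validation.  The default scheme is full (leave-one-out)
#' cross-validation: each sample is predicted by a model trained without
#' it.  `RMSEV(a) = sqrt(mean((yhat_-i - y_i)^2))`; R-squared values are
#' `1 - SS_res/SS_tot` with `SS_tot` about the overall mean (R2cal on
#' fitted values, R2val on the left-out predictions).  The chosen factor
#' count is the smallest `a` whose RMSEV is within `ratio` times the
#' minimum RMSEV (default `ratio = 1`, i.e. the global minimum).
#'
#' @param x numeric matrix (n x p) or a pretreated, replicate-averaged
#'   [SpectraSet-class] (calibration-role samples are used).
#' @param y response vector (taken from metadata for a SpectraSet).
#' @param maxFactors largest factor count to evaluate.
#' @param ratio factor-selection tolerance on RMSEV (>= 1).
#' @param segments optional list of index vectors defining cross-validation
#'   segments; default is leave-one-out.
#' @param ... passed to [fitNipals()].
#' @return A [CalibrationMetrics-class].
#' @rdname crossValidate
#' @export
setMethod("crossValidate", "matrix",
          function(x, y, maxFactors, ratio = 1, segments = NULL, ...) {
  X <- x
  n <- nrow(X)
  if (n < 3L) stop("design error: cross-validation requires n >= 3")
  if (is.null(segments)) segments <- as.list(seq_len(n))
  full <- fitNipals(X, y, maxFactors, ...)
  A <- full@nFactors
  fitted <- t(vapply(seq_len(n),
                     function(i) .pls_predict_path(full, X[i, ]),
                     numeric(A)))
  cvpred <- matrix(NA_real_, n, A)
  for (seg in segments) {
    subMax <- min(maxFactors, length(y) - length(seg) - 1L)
    sub <- fitNipals(X[-seg, , drop = FALSE], y[-seg], subMax, ...)
    for (i in seg) {
      path <- .pls_predict_path(sub, X[i, ])
      ## a sub-model supporting fewer factors keeps its last prediction
      cvpred[i, ] <- path[pmin(seq_len(A), length(path))]
    }
  }
  sstot <- sum((y - mean(y))^2)
  tab <- data.frame(
    factors = seq_len(A),
    rmsec = vapply(seq_len(A), function(a) .rmse(fitted[, a] - y), 0),
    r2cal = vapply(seq_len(A), function(a)
      1 - sum((fitted[, a] - y)^2) / sstot, 0),
    rmsev = vapply(seq_len(A), function(a) .rmse(cvpred[, a] - y), 0),
    r2val = vapply(seq_len(A), function(a)
      1 - sum((cvpred[, a] - y)^2) / sstot, 0)
  )
  chosen <- min(which(tab$rmsev <= ratio * min(tab$rmsev)))
  methods::new("CalibrationMetrics", table = tab,
               chosenFactors = as.integer(chosen))
})

#' @rdname crossValidate
#' @export
setMethod("crossValidate", "SpectraSet",
          function(x, maxFactors, ratio = 1, segments = NULL,
                   role = "calibration", ...) {
  meta <- sampleMeta(x)
  sel <- meta$role == role
  if (!any(sel)) stop("design error: no samples with role '", role, "'")
  crossValidate(spectraMatrix(x)[sel, , drop = FALSE],
                y = meta$concentration[sel], maxFactors = maxFactors,
                ratio = ratio, segments = segments, ...)
})

#' @rdname metricsTable
#' @param x a [CalibrationMetrics-class].
#' @return `metricsTable()`: the per-factor data.frame; `chosenFactors()`:
#'   the selected factor count.
#' @export
setMethod("metricsTable", "CalibrationMetrics", function(x) x@table)

#' @rdname metricsTable
#' @export
setMethod("chosenFactors", "CalibrationMetrics", function(x) x@chosenFactors)

setMethod("show", "CalibrationMetrics", function(object) {
  a <- object@chosenFactors
  row <- object@table[object@table$factors == a, ]
  cat("CalibrationMetrics over", nrow(object@table), "factor counts;",
      "chosen:", a, "\n")
  cat(sprintf("  RMSEC %.4g  R2cal %.6f  RMSEV %.4g  R2val %.6f\n",
              row$rmsec, row$r2cal, row$rmsev, row$r2val))
})

## ---- serialization --------------------------------------------------------

#' Serialize / restore a PLSModel as JSON
#'
#' Writes all centering vectors, factor matrices, the coefficient vector,
#' factor count and grid to a versioned JSON text file so that prediction
#' can run without refitting.
#'
#' @param model a [PLSModel-class].
#' @param path output (or input) file path.
#' @return `readPLSModel()` returns the restored [PLSModel-class].
#' @export
writePLSModel <- function(model, path) {
  obj <- list(
    format = "tpcNIR-pls-model", version = 1L,
    x_mean = model@xMean, y_mean = model@yMean,
    weights = model@weights, scores = model@scores,
    x_loadings = model@xLoadings, y_loadings = model@yLoadings,
    coefficients = model@coefficients, n_factors = model@nFactors,
    wavenumbers = model@wavenumbers
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(NULL)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tpcNIR-pls-model"))
    stop("format error: not a serialized PLS model")
  methods::new("PLSModel",
    xMean = as.numeric(obj$x_mean), yMean = as.numeric(obj$y_mean),
    weights = as.matrix(obj$weights), scores = as.matrix(obj$scores),
    xLoadings = as.matrix(obj$x_loadings),
    yLoadings = as.numeric(obj$y_loadings),
    coefficients = as.numeric(obj$coefficients),
    nFactors = as.integer(obj$n_factors),
    wavenumbers = as.numeric(obj$wavenumbers))
}
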