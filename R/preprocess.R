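## Spectral pretreatment operators.  All operators act row-wise (one spectrum
## at a time) and are therefore invariant to sample permutation.

.set_matrix <- function(x, m) {
  ## replace the absorbance matrix (samples x wavenumbers) of a SpectraSet
  SpectraSet(m, wavenumbers(x), sampleMeta(x))
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to zero mean and unit standard deviation
#' (n-1 denominator): `x -> (x - mean(x)) / sd(x)`.
#'
#' @param x a [SpectraSet-class] with at least 2 wavenumbers per spectrum.
#' @return The transformed [SpectraSet-class]; every row has mean 0 and
#'   sd 1 to within 1e-12.
#' @rdname snv
#' @export
setMethod("snv", "SpectraSet", function(x) {
  m <- spectraMatrix(x)
  if (ncol(m) < 2L)
    stop("degenerate-spectrum error: SNV requires at least 2 points")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  if (any(sdv == 0))
    stop("degenerate-spectrum error: constant spectrum has zero variance")
  .set_matrix(x, (m - mu) / sdv)
})

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * reference`,
#' and returns `(x - a) / b`.  The reference defaults to the column-wise
#' mean spectrum of the set; the reference itself is corrected to identity.
#'
#' @param x a [SpectraSet-class].
#' @param reference optional numeric reference spectrum (length = number of
#'   wavenumbers); defaults to the mean spectrum.
#' @return The corrected [SpectraSet-class].
#' @rdname msc
#' @export
setMethod("msc", "SpectraSet", function(x, reference = NULL) {
  m <- spectraMatrix(x)
  if (is.null(reference)) reference <- colMeans(m)
  if (length(reference) != ncol(m))
    stop("shape error: reference length must match the wavenumber count")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss == 0)
    stop("degenerate-reference error: reference spectrum has zero variance")
  b <- as.numeric(m %*% rc) / ss           # per-row slope
  a <- rowMeans(m) - b * mean(reference)   # per-row intercept
  if (any(b == 0))
    stop("degenerate-spectrum error: zero regression slope in MSC")
  .set_matrix(x, (m - a) / b)
})

#' Polynomial detrending
#'
#' Subtracts from each spectrum its least-squares polynomial of the given
#' degree in the wavenumber index; the residual is orthogonal to that
#' polynomial basis.  Degree 0 is mean removal.
#'
#' @param x a [SpectraSet-class].
#' @param degree polynomial degree, one of 0, 1, 2.
#' @return The detrended [SpectraSet-class].
#' @rdname detrendSpectra
#' @export
setMethod("detrendSpectra", "SpectraSet", function(x, degree = 1L) {
  if (!degree %in% 0:2)
    stop("parameter error: detrend degree must be 0, 1 or 2")
  m <- spectraMatrix(x)
  p <- ncol(m)
  if (p <= degree)
    stop("parameter error: spectrum length must exceed the detrend degree")
  idx <- seq_len(p)
  basis <- cbind(rep(1, p))
  if (degree >= 1L) basis <- cbind(basis, stats::poly(idx, degree))
  q <- qr.Q(qr(basis))
  .set_matrix(x, m - (m %*% q) %*% t(q))
})

#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay filter to each spectrum: local least-squares
#' polynomial of order `polyorder` on a centered window of `window` points,
#' evaluated (or differentiated `derivorder` times) at the window center.
#' Edges are handled by polynomial fits on the truncated windows.
#' `polyorder = 0, derivorder = 0` equals a centered moving average.
#' Derivatives are scaled by the signed grid spacing so that units are per
#' cm-1 along the wavenumber axis.
#'
#' @param x a [SpectraSet-class].
#' @param window odd window length in points, greater than `polyorder` and
#'   at most the spectrum length.
#' @param polyorder local polynomial order (>= `derivorder`).
#' @param derivorder derivative order, one of 0 (smoothing), 1, 2.
#' @return The filtered [SpectraSet-class].
#' @rdname sgFilter
#' @export
setMethod("sgFilter", "SpectraSet", function(x, window, polyorder,
                                             derivorder = 0L) {
  if (window %% 2L != 1L)
    stop("parameter error: Savitzky-Golay window must be odd")
  if (window <= polyorder)
    stop("parameter error: window must exceed the polynomial order")
  if (!derivorder %in% 0:2)
    stop("parameter error: derivative order must be 0, 1 or 2")
  if (polyorder < derivorder)
    stop("parameter error: polynomial order must be >= derivative order")
  m <- spectraMatrix(x)
  if (window > ncol(m))
    stop("parameter error: window larger than the spectrum")
  ts <- if (derivorder > 0L) gridSpacing(x) else 1
  out <- t(apply(m, 1L, function(row)
    signal::sgolayfilt(row, p = polyorder, n = window, m = derivorder,
                       ts = ts)))
  .set_matrix(x, out)
})

## ---- pretreatment plans ---------------------------------------------------

.PLAN_KINDS <- c("snv", "msc", "detrend", "sg", "reduce")

#' Build a pretreatment plan
#'
#' A plan is an ordered list of steps, each a list with a `kind` (one of
#' `"snv"`, `"msc"`, `"detrend"`, `"sg"`, `"reduce"`) and kind-specific
#' parameters.  The packaged `"reference"` preset is the chain
#' detrend(degree 1) -> region reduction -> Savitzky-Golay smoothing
#' (polynomial order 0, 19 points) -> SNV, the default workflow for spectra
#' of sorbent-bound polyphenols.  Plans serialize losslessly to YAML in the
#' pipeline configuration.
#'
#' @param preset `"reference"` for the packaged chain, `"linear"` for the
#'   same chain without the final SNV (all steps linear maps), or `NULL`
#'   to pass `steps` directly.
#' @param steps list of step lists (used when `preset` is `NULL`).
#' @param regions region matrix used by any `"reduce"` step of the preset
#'   (default [defaultRegions()]).
#' @return An object of class `preprocess_plan` (a list of steps).
#' @examples
#' plan <- preprocessPlan("reference")
#' vapply(plan, `[[`, "", "kind")
#' @export
preprocessPlan <- function(preset = NULL, steps = NULL,
                           regions = defaultRegions()) {
  if (!is.null(preset)) {
    steps <- switch(preset,
      reference = list(
        list(kind = "detrend", degree = 1L),
        list(kind = "reduce", regions = regions),
        list(kind = "sg", window = 19L, polyorder = 0L, derivorder = 0L),
        list(kind = "snv")
      ),
      ## "linear": the reference chain without SNV; every step is a linear
      ## map, so spectra that are linear in concentration stay linear
      linear = list(
        list(kind = "detrend", degree = 1L),
        list(kind = "reduce", regions = regions),
        list(kind = "sg", window = 19L, polyorder = 0L, derivorder = 0L)
      ),
      stop("parameter error: unknown preset '", preset, "'")
    )
  }
  if (is.null(steps)) steps <- list()
  for (st in steps) {
    if (is.null(st$kind) || !st$kind %in% .PLAN_KINDS)
      stop("parameter error: each step needs a kind in: ",
           paste(.PLAN_KINDS, collapse = ", "))
  }
  structure(steps, class = "preprocess_plan")
}

#' Apply a pretreatment plan to a SpectraSet
#'
#' Steps run in order; an empty plan is the identity.
#'
#' @param x a [SpectraSet-class].
#' @param plan a plan from [preprocessPlan()].
#' @return The pretreated [SpectraSet-class].
#' @rdname applyPlan
#' @export
setMethod("applyPlan", "SpectraSet", function(x, plan) {
  for (st in plan) {
    x <- switch(st$kind,
      snv = snv(x),
      msc = msc(x, reference = st$reference),
      detrend = detrendSpectra(x, degree = if (is.null(st$degree)) 1L else st$degree),
      sg = sgFilter(x, window = st$window, polyorder = st$polyorder,
                    derivorder = if (is.null(st$derivorder)) 0L else st$derivorder),
      reduce = reduceRegions(x, if (is.null(st$regions)) defaultRegions()
                                else st$regions),
      stop("parameter error: unknown step kind '", st$kind, "'")
    )
  }
  x
})

## plan <-> plain-list conversion for YAML config round-trips
.plan_to_list <- function(plan) {
  lapply(plan, function(st) {
    if (identical(st$kind, "reduce") && !is.null(st$regions)) {
      st$regions <- lapply(seq_len(nrow(st$regions)),
                           function(i) as.numeric(st$regions[i, ]))
    }
    st
  })
}

.plan_from_list <- function(lst) {
  steps <- lapply(lst, function(st) {
    if (identical(st$kind, "reduce") && !is.null(st$regions))
      st$regions <- do.call(rbind, lapply(st$regions, as.numeric))
    st
  })
  preprocessPlan(steps = steps)
}
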