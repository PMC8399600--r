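## Method-validation statistics: recovery, dispersion summaries, confidence
## intervals and the selectivity study layout.

#' Recovery rate
#'
#' `recovery = 100 * measured / nominal` (percent).  Vectorized over
#' `measured`.
#'
#' @param measured measured concentration(s), mg L-1.
#' @param nominal nominal (spiked/standard) concentration, mg L-1, > 0.
#' @return Recovery in percent (full precision; reports round to 1 decimal).
#' @export
recoveryRate <- function(measured, nominal) {
  if (any(nominal <= 0))
    stop("parameter error: nominal concentration must be positive")
  100 * measured / nominal
}

#' Dispersion summary of replicate determinations
#'
#' Mean, standard deviation (n-1 denominator), relative standard deviation
#' `RSD = 100 * sd / mean` and standard error of the mean `sem = sd /
#' sqrt(n)`.
#'
#' @param values numeric vector, n >= 2 (sd-dependent fields need spread
#'   information).
#' @return A list with elements `n`, `mean`, `sd`, `rsd_percent`, `sem`.
#' @export
summarizeValues <- function(values) {
  n <- length(values)
  if (n < 2L)
    stop("sample-size error: at least 2 values are needed for sd")
  m <- mean(values)
  s <- stats::sd(values)
  list(n = n, mean = m, sd = s,
       rsd_percent = if (m != 0) 100 * s / m else 0,
       sem = s / sqrt(n))
}

#' Normal-quantile confidence interval for a mean
#'
#' `mean +/- z * sd / sqrt(n)`; the default `z = 1.96` corresponds to
#' `alpha = 0.05`.
#'
#' @param stats a summary from [summarizeValues()] (or any list with
#'   `mean`, `sd`, `n`).
#' @param z normal quantile (default 1.96).
#' @return A list with `lower`, `upper`, `z`, `alpha`.
#' @export
confidenceInterval <- function(stats, z = 1.96) {
  if (is.null(stats$n) || stats$n < 2L)
    stop("sample-size error: confidence interval requires n >= 2")
  half <- z * stats$sd / sqrt(stats$n)
  list(lower = stats$mean - half, upper = stats$mean + half,
       z = z, alpha = 2 * stats::pnorm(-abs(z)))
}

#' Selectivity study summary
#'
#' Summarizes a control determination and spiked determinations (one vector
#' of measured concentrations per interfering substance) into the two-row
#' layout used in selectivity reporting: a concentration row (mean, sd) and
#' a recovery row (mean recovery %, sd of recovery %), one column block per
#' condition.
#'
#' @param control measured concentrations for the unspiked control, n >= 2.
#' @param spiked named list of measured-concentration vectors, one per
#'   interfering substance.
#' @param nominal nominal concentration of the standard, mg L-1.
#' @return data.frame with one row per condition (control first) and
#'   columns `condition`, `n`, `mean`, `sd`, `sem`, `rsd_percent`,
#'   `recovery_percent`, `recovery_sd`.
#' @export
selectivityReport <- function(control, spiked, nominal) {
  if (missing(control) || is.null(control))
    stop("design error: a control determination is required")
  conditions <- c(list(control = control), as.list(spiked))
  rows <- lapply(names(conditions), function(nm) {
    v <- conditions[[nm]]
    st <- summarizeValues(v)
    data.frame(condition = nm, n = st$n, mean = st$mean, sd = st$sd,
               sem = st$sem, rsd_percent = st$rsd_percent,
               recovery_percent = recoveryRate(st$mean, nominal),
               recovery_sd = 100 * st$sd / nominal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
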