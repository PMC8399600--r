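## Calculators for the comparison methods: sorbent adsorption capacity,
## linear (Folin-Ciocalteu / HPLC) calibration math, and the Loewenthal
## permanganate-titration conversion.

#' Sorbent adsorption capacity
#'
#' `q = (C0 - Ce) * V / M` in mg analyte per g sorbent.
#'
#' @param c0 initial concentration, mg L-1.
#' @param ce equilibrium concentration, mg L-1 (0 <= ce <= c0).
#' @param volume solution volume, L (> 0).
#' @param mass sorbent mass, g (> 0).
#' @return Adsorption capacity in mg g-1.
#' @examples
#' adsorptionCapacity(200, 5.6, 0.004, 0.1)  # 7.776 mg g-1
#' @export
adsorptionCapacity <- function(c0, ce, volume, mass) {
  if (any(ce < 0) || any(c0 < 0))
    stop("parameter error: concentrations must be non-negative")
  if (any(ce > c0))
    stop("physical-consistency error: equilibrium exceeds initial concentration")
  if (volume <= 0 || mass <= 0)
    stop("parameter error: volume and mass must be positive")
  (c0 - ce) * volume / mass
}

#' Ordinary least-squares calibration line
#'
#' Fits `signal ~ intercept + slope * concentration` for photometric or
#' chromatographic quantification (e.g. Folin-Ciocalteu at 765 nm, HPLC-UV
#' at 276 nm).
#'
#' @param x standard concentrations, mg L-1 (>= 2 distinct values).
#' @param y measured signals.
#' @return A list of class `linear_calibration` with `slope`, `intercept`,
#'   `r_squared`.
#' @seealso [predictInverse()]
#' @export
fitLinearCalibration <- function(x, y) {
  if (length(x) != length(y))
    stop("shape error: x and y must have equal length")
  if (length(unique(x)) < 2L)
    stop("fit error: need at least 2 distinct standard concentrations")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "linear_calibration")
}

#' Inverse prediction from a calibration line
#'
#' `concentration = (signal - intercept) / slope`.
#'
#' @param cal a `linear_calibration` (or any list with `slope`,
#'   `intercept`).
#' @param signal measured signal(s).
#' @return Concentration(s) in mg L-1.
#' @export
predictInverse <- function(cal, signal) {
  if (cal$slope == 0) stop("fit error: zero slope has no inverse")
  (signal - cal$intercept) / cal$slope
}

#' Loewenthal titration conversion factor
#'
#' `F = cGA * Vs / ((Vt - Vb) * c * t)` from titration of a gallic acid
#' standard.  Vectorized over the standards; see
#' [calibrateLoewenthal()] for the multi-standard aggregate.
#'
#' @param cGA standard concentration, mg L-1 GAE.
#' @param vs sample volume, mL.
#' @param vt titrant volume for the sample, mL.
#' @param vb titrant volume for the blank, mL.
#' @param c permanganate concentration, mol L-1.
#' @param t titer of the permanganate solution.
#' @return Conversion factor F.
#' @export
loewenthalFactor <- function(cGA, vs, vt, vb, c, t) {
  if (any(vt <= vb))
    stop("titration error: sample titration volume must exceed the blank")
  if (c <= 0 || any(t <= 0))
    stop("parameter error: permanganate concentration and titer must be positive")
  cGA * vs / ((vt - vb) * c * t)
}

#' Multi-standard Loewenthal calibration
#'
#' Computes one conversion factor per standard titration and aggregates by
#' the arithmetic mean, reporting its standard deviation alongside.
#'
#' @param standards data.frame with columns `cGA`, `vs`, `vt`, `vb`
#'   (volumes in mL).
#' @param c,t permanganate concentration (mol L-1) and titer.
#' @return A list with `F_mean`, `F_sd`, `F_values`.
#' @export
calibrateLoewenthal <- function(standards, c, t) {
  if (nrow(standards) < 2L)
    stop("design error: Loewenthal calibration needs >= 2 standards")
  f <- loewenthalFactor(standards$cGA, standards$vs, standards$vt,
                        standards$vb, c, t)
  list(F_mean = mean(f), F_sd = stats::sd(f), F_values = f)
}

#' Total polyphenol content from a Loewenthal titration
#'
#' `content = (Vt - Vb) * c * t * F / Vs`, mg L-1 GAE; the algebraic
#' inverse of [loewenthalFactor()].
#'
#' @param f conversion factor.
#' @param vt,vb sample and blank titrant volumes, mL (`vt >= vb`).
#' @param c,t permanganate concentration (mol L-1) and titer.
#' @param vs sample volume, mL.
#' @return Polyphenol content, mg L-1 GAE.
#' @export
polyphenolContent <- function(f, vt, vb, c, t, vs) {
  if (any(vt < vb))
    stop("titration error: sample titration volume below the blank")
  if (c <= 0 || any(t <= 0))
    stop("parameter error: permanganate concentration and titer must be positive")
  (vt - vb) * c * t * f / vs
}
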