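---
title: "Methods: NIR prediction of total polyphenolic content on a PVP solid phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR prediction of total polyphenolic content on a PVP solid phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcNIR)
```

## The measurement problem

Total polyphenolic content (TPC) is a sum parameter: thousands of phenolic
structures are reported jointly as gallic acid equivalents (GAE, mg L⁻¹).
The workflow this package supports binds the phenols of a liquid sample to
insoluble polyvinylpyrrolidone (PVP) by dispersive solid-phase extraction
(hydrogen bonding between the PVP carbonyl and the phenolic hydroxyl),
freeze-dries the loaded sorbent and records its near-infrared
diffuse-reflectance spectrum on a 10,000–4000 cm⁻¹ grid at 8 cm⁻¹ steps.
Because the analyte signal is spread over many overlapping overtone and
combination bands, quantification is multivariate: a PLS1 regression maps
the pretreated spectrum to concentration.

The package assumes the grid is stored in descending instrument order with
a uniform base step; the stated instrument "resolution of 8 cm⁻¹" is
equated with the sampling interval (the two need not coincide on every
instrument, but nothing downstream depends on the distinction). A
region-reduced spectrum keeps its base step and simply carries gaps that
are integer multiples of it; the validity check enforces exactly that.

## Pretreatment

Diffuse-reflectance spectra of a powder carry strong multiplicative and
additive scatter effects from non-uniform particle size. Four operators are
provided, each acting on one spectrum at a time (hence trivially invariant
to sample order):

* **SNV** — per-spectrum centering and scaling to unit standard deviation.
  The standard deviation uses the *n − 1* denominator; tests pin this
  convention. A constant spectrum is rejected rather than silently mapped
  to zero.
* **MSC** — per-spectrum affine regression on a reference (default: the
  set's mean spectrum), then inversion of slope and intercept. A
  zero-variance reference is rejected.
* **Detrending** — subtraction of a per-spectrum least-squares polynomial
  in the wavenumber index, degree 0–2. The default degree in the packaged
  chain is 1 (linear); the choice is an assumption, exposed as a
  parameter, since baseline curvature varies between instruments.
* **Savitzky–Golay** — local polynomial convolution for smoothing or
  first/second derivatives. Window must be odd and larger than the
  polynomial order. Edges are handled by least-squares fits on the
  truncated windows (the `signal` package's transient filters) rather than
  padding, so polynomial rows are reproduced exactly up to the boundary.
  Derivatives are divided by the signed grid step, giving units per cm⁻¹
  on the descending axis.

The packaged `"reference"` preset chains detrend(1) → region reduction →
SG(order 0, 19 points; a centered moving average) → SNV, with replicate
scans averaged **after** pretreatment — the pipeline enforces this order
and the configuration cannot move averaging earlier. Region reduction keeps
the closed intervals 5344–9612 and 4068–4960 cm⁻¹: the excluded
4960–5344 cm⁻¹ window is the OH combination band of residual moisture
(freeze-drying never removes all water), and the grid ends are excluded for
their high noise. "Reduction" is implemented as region exclusion only, not
down-sampling. A `"linear"` preset (the same chain without SNV) is provided
because every step in it is a linear map — useful for exactness checks and
for data with negligible scatter.

## Calibration and model selection

PLS1 is fitted by the classical NIPALS recursion on mean-centered data
(no variance scaling — channels share units, standard practice for
spectra). For a single response the weight update converges in one pass;
the iteration guard (tolerance 1e-10 on the weight change, cap 500)
future-proofs a multi-response extension. When deflation exhausts the data
early — noiseless low-rank inputs — the model truncates to the supported
factor count instead of amplifying numerical noise into spurious factors.
A constant response or a zero weight vector raises a degeneracy error.

"Full cross-validation" is interpreted as leave-one-out; segmented
cross-validation is available through the configuration. RMSEC/R²cal are
computed on fitted values, RMSEV/R²val on the left-out predictions, both
R² as 1 − SS_res/SS_tot about the overall mean (the cross-validated R² is
reported; a separately held-out validation set can be evaluated with
`predict`). The selected factor count is the smallest one whose RMSEV is
within a configurable ratio of the global minimum; the default ratio of 1
makes the rule "first global minimum", and a fixed user override is
available to emulate a predetermined factor count.

## Figures of merit

Sensitivity is `SEN = 1/‖b‖₂`. The background leverage of calibration
sample *n* removes the analyte contribution from its score vector,
`t0_n = t_n − y_cen,n · s` with `s` the least-squares regression of each
score column on the centered concentrations, and normalizes per factor:
`h0_n = Σ_a t0_na² / Σ_m t_ma²`. This operational formula is pinned in the
test suite by an independently coded brute-force loop, and its invariances
(sample permutation, uniform scaling of X) are tested as properties.

The detection limit combines instrument-signal variance propagated through
the sensitivity with the calibration-concentration variance weighted by the
leverage: `LOD = 3.3·[SEN⁻²var(x) + h0·SEN⁻²var(x) + h0·var(y_cal)]^½`,
evaluated at `h0_min` and `h0_max`; `LOQ = 3·LOD`, and the working range is
`[LOQ_min, max calibration concentration]`. The estimator behind `var(x)`
is not uniquely defined by the approach; the package defaults to the mean
squared X-residual after reconstruction from the model's factors, averaged
over the calibration spectra, and accepts a user-supplied estimate (e.g.
blank-replicate variance) instead. Note that the multivariate LOQ/LOD ratio
is exactly 3 by definition, whereas univariate (3.3σ/10σ) limits quoted for
photometric or titrimetric methods carry a ratio of 10/3.3 ≈ 3.03 — the two
conventions should not be mixed when comparing methods.

## Validation statistics

Recovery is `100·measured/nominal`; dispersion summaries report sd (n − 1),
RSD and SEM separately and never ambiguously (published validation tables
sometimes label an sd-consistent dispersion "± SEM"; keeping both avoids
the ambiguity). The confidence interval is the normal-quantile form
`mean ± z·sd/√n` with z = 1.96 by default (α = 0.05). The selectivity
report reproduces the two-row layout of a spiking study: a concentration
row (mean, sd) and a recovery row, per condition, which are mutually
consistent under the recovery definition by construction. Reports round to
one decimal; all internal computation keeps full precision.

## Reference-method calculators

Ordinary least squares serves both the Folin–Ciocalteu photometric curve
(signal at 765 nm vs concentration) and HPLC-UV quantification
(2.5–25 mg L⁻¹ design), with inverse prediction
`(signal − intercept)/slope`. The Löwenthal conversion factor
`F = c_GA·V_s/((V_t−V_b)·c·t)` is aggregated over a multi-standard
titration design by the arithmetic mean of per-standard factors (the
aggregation rule is a package choice; the sd across standards is reported
alongside). The content equation is its exact algebraic inverse, and the
round-trip is tested to 1e-12. Adsorption capacity is `q = (C₀−C_e)·V/M`;
equilibrium above initial concentration is a physical-consistency error.

## The synthetic-data generator

No real spectra are distributed with the package, so the generator is a
first-class module that defines the study conditions for every test:

* **Design** — gallic acid levels 0–300 mg L⁻¹ in 25 mg L⁻¹ steps, four
  extraction replicates per level (52 calibration points; the extension to
  500 mg L⁻¹ is a design parameter), three scans per extraction,
  extraction at pH 3.5 with 4 mL sample and 100 mg sorbent. The adsorbed
  amount is `concentration × fraction(pH) × V/M` with hard-coded fractions
  0.974 (pH 3.5), 0.303 (pH 6), 0.359 (pH 8); an uncalibrated pH is an
  error, not an interpolation.
* **Signal** — Gaussian bands (centers mid-way inside the six
  analyte-correlated regions between 4350 and 8040 cm⁻¹, σ = region
  width/4; band amplitudes are free parameters of the generator), a broad
  sorbent background, and a residual-water band at 5152 cm⁻¹ whose
  amplitude varies per sample — deliberately overlapping the excluded
  water region so that region exclusion has something real to remove.
* **Noise** — per-scan multiplicative scatter (sd 0.08 around 1), baseline
  offset and tilt (sd 0.03 each), additive noise (sd 0.018 absorbance
  units), and extra noise (sd 0.06) outside 4068–9612 cm⁻¹ so the spectral
  ends are measurably worse — the generator reproduces the rationale for
  excluding them. Defaults were calibrated once so that the default
  pipeline on the 52-point design sits at R²cal ≈ 0.999 — the regime a
  well-behaved bench calibration of this kind occupies — and are not
  otherwise meaningful.
* **Determinism** — one integer seed; each scan draws from a substream
  derived by counter, so generating a subset of a design reproduces the
  same spectra.
* **Interference mechanisms** — ascorbic acid and tyrosine do not bind PVP
  at pH 3.5 and are washed away: their selectivity sets carry no
  mechanism, and tests only check they behave like the control. Glucose at
  high concentration is partly retained: modeled as carbohydrate-band
  contamination plus extra scatter spread (sticky residue, non-uniform
  particles), which biases recovery and inflates its sd — the pattern is
  asserted as a sign test across seeds, not as specific percentages.

What the generator does **not** emulate: radiative-transfer physics of
diffuse reflectance (no Kubelka–Munk), instrument line shape, wavelength
drift, temperature effects, band-shape differences between adsorbed and
free analyte, or matrix-dependent adsorption competition. Passing tests
therefore demonstrate correctness of the computational chain under a
realistic statistical structure, not predictive validity on any real
instrument's data.

## A note on SNV and exactness in the noiseless limit

With all noise off, generated spectra are exactly linear in concentration,
and through the `"linear"` preset the PLS fit recovers the truth to
machine precision — the package's strongest correctness check. Under the
full `"reference"` preset this exactness is *structurally* unavailable:
SNV divides each spectrum by its own standard deviation, which itself
depends on concentration, so the family `u + c·v` maps into the
two-dimensional span of {centered u, centered v} with coordinates that are
nonlinear in c. Centered X then has rank 2, and no linear model in any
number of factors can reproduce c exactly; the residual is a small
curvature floor (well below half a percent of the calibration range at the
packaged settings, asserted in the tests). This is an intrinsic property
of scatter-normalizing pretreatments, worth remembering when interpreting
"noiseless" benchmarks of SNV-terminated pipelines.

## Numerical choices and degenerate inputs

* CSV round-trips preserve absorbances to better than 1e-12 relative
  (17 significant digits written).
* Region bounds are closed intervals; a wavenumber is kept iff it lies
  inside some interval; an empty selection is an error.
* Replicate groups must agree on concentration and role; conflicts are
  metadata errors rather than silent averaging.
* Factor-count tie-break: the smallest factor count attaining the RMSEV
  criterion.
* Leverage computation with all-equal concentrations degrades gracefully
  to the ordinary score leverage (no analyte direction to remove).
* All validity failures and parameter errors carry stable, prefixed
  messages (`grid error:`, `format error:`, `parameter error:`, …) that
  the pipeline maps onto stage-tagged failures.

## Problem sizes

The test suite and acceptance script run the full 52-sample × 751-channel
design (156 scans) for end-to-end checks, with leave-one-out
cross-validation up to 8–12 factors; property tests use 5 noise levels × 5
seeds for the noise-monotonicity study, 10 seeds for the interference sign
tests and 20 random instances for the PLS-oracle equivalence. These sizes
were chosen to exercise the same shapes as a bench study of this design.

## Known limitations

* PLS2 (multivariate response), sparse/kernel PLS and variable selection
  beyond region specification are out of scope.
* The univariate (ICH-style) LOD is not implemented; only the multivariate
  interval-valued limits are.
* No JCAMP-DX or proprietary instrument formats; CSV only, no
  interpolation between grids.
* Titration stoichiometry is not modeled; the Löwenthal module only
  implements the conversion-factor bookkeeping.
* The generator's band amplitudes for the adsorbed analyte are free
  parameters constrained only by the documented spectral regions; absolute
  figures of merit computed on synthetic data characterize the generator's
  regime, not any particular instrument.
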