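## Synthetic NIR spectra with known ground truth.
##
## The generator emulates diffuse-reflectance spectra of gallic acid
## adsorbed on a polyvinylpyrrolidone sorbent: a broad sorbent background,
## analyte bands in the regions where gallic acid correlates with
## concentration, a residual-water OH band (4960-5344 cm-1), per-sample
## multiplicative scatter (non-uniform particle size), baseline offset and
## tilt, additive noise, and extra noise at the spectral ends (outside
## 4068-9612 cm-1).  All draws derive from one seed via per-scan
## substreams, so any subset of a design is reproducible.

#' Standard instrument wavenumber grid
#'
#' Descending grid from `from` to `to` cm-1 in steps of `by` (default
#' 10000 to 4000 at 8 cm-1, the acquisition convention assumed throughout).
#'
#' @param from,to grid bounds in cm-1 (`from > to`).
#' @param by step in cm-1 (> 0).
#' @return Numeric descending vector.
#' @export
nirGrid <- function(from = 10000, to = 4000, by = 8) {
  if (from <= to || by <= 0) stop("grid error: need from > to and by > 0")
  seq(from, to, by = -by)
}

#' Component spectrum definition
#'
#' A named set of Gaussian bands with a role in the mixture model.
#'
#' @param name component name.
#' @param bands data.frame with columns `center` (cm-1, within
#'   4000-10000), `width` (cm-1, > 0; the Gaussian sigma) and `amplitude`.
#' @param role one of `"sorbent_background"`, `"analyte"`, `"water"`,
#'   `"interferent"`.
#' @return A list of class `component_spectrum`.
#' @export
componentSpectrum <- function(name, bands,
                              role = c("sorbent_background", "analyte",
                                       "water", "interferent")) {
  role <- match.arg(role)
  bands <- as.data.frame(bands)
  if (nrow(bands)) {
    if (any(bands$center < 4000 | bands$center > 10000))
      stop("parameter error: band centers must lie within [4000, 10000] cm-1")
    if (any(bands$width <= 0))
      stop("parameter error: band widths must be positive")
  }
  structure(list(name = name, bands = bands, role = role),
            class = "component_spectrum")
}

#' Evaluate a component spectrum on a grid
#'
#' Sum of Gaussian bands `amplitude * exp(-(w - center)^2 / (2 width^2))`;
#' non-negative, zero for an empty band list.
#'
#' @param component a [componentSpectrum()].
#' @param grid numeric wavenumber vector.
#' @return Numeric spectrum on `grid`.
#' @export
gaussianSpectrum <- function(component, grid) {
  out <- numeric(length(grid))
  b <- component$bands
  for (i in seq_len(nrow(b)))
    out <- out + b$amplitude[i] *
      exp(-(grid - b$center[i])^2 / (2 * b$width[i]^2))
  out
}

#' Packaged component presets
#'
#' The built-in mixture components.  Analyte bands sit mid-way inside the
#' concentration-correlated regions 4350-4400, 4500-4640, 5000-5320,
#' 6000-6550, 6900-7330 and 7360-8040 cm-1, with sigma = region width / 4;
#' amplitudes are per unit adsorbed analyte (mg g-1).  The water component
#' is the residual-moisture OH combination band centered in 4960-5344 cm-1
#' (which is why that region is excluded from model building).  The sorbent
#' background is a set of broad bands plus a near-constant baseline.  The
#' glucose interferent carries carbohydrate bands overlapping the analyte
#' regions.
#'
#' @return Named list of `component_spectrum` objects:
#'   `sorbent`, `analyte`, `water`, `glucose`.
#' @export
componentPresets <- function() {
  list(
    sorbent = componentSpectrum("pvp_background", data.frame(
      center = c(7000, 4680, 5800, 6450, 7050, 8300, 9300),
      width = c(4000, 350, 450, 300, 500, 600, 500) / 4,
      amplitude = c(0.85, 0.45, 0.30, 0.20, 0.18, 0.10, 0.06)),
      role = "sorbent_background"),
    analyte = componentSpectrum("gallic_acid", data.frame(
      center = c(4375, 4570, 5160, 6275, 7115, 7700),
      width = c(50, 140, 320, 550, 430, 680) / 4,
      amplitude = c(0.012, 0.016, 0.014, 0.018, 0.012, 0.010)),
      role = "analyte"),
    water = componentSpectrum("residual_water", data.frame(
      center = 5152, width = 96, amplitude = 1),
      role = "water"),
    glucose = componentSpectrum("glucose", data.frame(
      center = c(4390, 4750, 5190, 6850),
      width = c(40, 60, 90, 130),
      amplitude = c(1, 0.8, 0.9, 0.5)),
      role = "interferent")
  )
}

#' Noise model for synthetic spectra
#'
#' @param additive_sd per-point additive noise sd, absorbance units.
#' @param scatter_slope_sd sd of the per-scan multiplicative scatter factor
#'   around 1 (non-uniform particle size).
#' @param baseline_offset_sd sd of the per-scan baseline offset.
#' @param baseline_tilt_sd sd of a per-scan linear baseline tilt (total
#'   absorbance change across the grid).
#' @param edge_noise_sd extra additive noise sd applied outside
#'   `[4068, 9612]` cm-1 (the noisy spectral ends).
#' @param water_amplitude_range `[low, high]` of the per-sample uniform
#'   residual-moisture amplitude.
#' @return A list of class `noise_model`.
#' @export
noiseModel <- function(additive_sd = 0.018,
                       scatter_slope_sd = 0.08,
                       baseline_offset_sd = 0.03,
                       baseline_tilt_sd = 0.03,
                       edge_noise_sd = 0.06,
                       water_amplitude_range = c(0.02, 0.45)) {
  vals <- c(additive_sd, scatter_slope_sd, baseline_offset_sd,
            baseline_tilt_sd, edge_noise_sd)
  if (any(vals < 0))
    stop("parameter error: noise standard deviations must be non-negative")
  if (length(water_amplitude_range) != 2L ||
      water_amplitude_range[1L] > water_amplitude_range[2L] ||
      any(water_amplitude_range < 0))
    stop("parameter error: water_amplitude_range must be [low, high] >= 0")
  structure(list(additive_sd = additive_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_tilt_sd = baseline_tilt_sd,
                 edge_noise_sd = edge_noise_sd,
                 water_amplitude_range = water_amplitude_range),
            class = "noise_model")
}

#' Zero-noise model
#'
#' All noise sources off and the residual-water amplitude fixed at its
#' default midpoint, so spectra are exactly linear in concentration.
#' @return A `noise_model`.
#' @export
zeroNoiseModel <- function()
  noiseModel(0, 0, 0, 0, 0, water_amplitude_range = c(0.235, 0.235))

#' Extraction recovery fraction at a calibrated pH
#'
#' The hydrogen-bond-driven adsorption on the sorbent was calibrated at
#' three pH values: fraction 0.974 at pH 3.5, 0.303 at pH 6 and 0.359 at
#' pH 8.  Intermediate pH values are not interpolated.
#'
#' @param ph one of 3.5, 6, 8.
#' @return Adsorbed fraction in `[0, 1]`.
#' @export
adsorptionFraction <- function(ph) {
  tab <- c("3.5" = 0.974, "6" = 0.303, "8" = 0.359)
  key <- format(ph, trim = TRUE)
  if (!key %in% names(tab))
    stop("parameter error: no calibrated adsorption fraction for pH ", ph)
  unname(tab[key])
}

#' Study design for a synthetic calibration
#'
#' The default reproduces the standard calibration design: gallic acid
#' levels 0 to 300 mg L-1 in 25 mg L-1 steps, four extraction replicates
#' per level (52 calibration points), three spectral scans per extraction,
#' extraction at pH 3.5 with 4 mL sample volume and 100 mg sorbent.
#'
#' @param concentrations vector of per-sample true concentrations, mg L-1
#'   (one entry per extraction replicate).
#' @param scansPerSample spectral scans per extraction (averaged after
#'   pretreatment).
#' @param ph extraction pH (must have a calibrated adsorption fraction).
#' @param volumeL sample volume in L.
#' @param massG sorbent mass in g.
#' @param role metadata role given to the generated samples.
#' @param seed integer seed controlling every stochastic draw.
#' @return A list of class `study_design`.
#' @export
studyDesign <- function(concentrations = rep(seq(0, 300, by = 25), each = 4),
                        scansPerSample = 3L, ph = 3.5,
                        volumeL = 0.004, massG = 0.1,
                        role = "calibration", seed = 1L) {
  if (any(concentrations < 0))
    stop("parameter error: concentrations must be non-negative")
  adsorptionFraction(ph)  # errors early on an uncalibrated pH
  structure(list(concentrations = as.numeric(concentrations),
                 scansPerSample = as.integer(scansPerSample),
                 ph = ph, volumeL = volumeL, massG = massG,
                 role = role, seed = as.integer(seed)),
            class = "study_design")
}

## deterministic substream: run expr under a seed derived from (seed, counter)
## without disturbing the caller's RNG state
.with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  sub <- (as.double(seed %% 65536L) * 30011 + as.double(counter) * 7919 +
          1299709) %% 2147483647
  set.seed(as.integer(sub))
  force(expr)
}

#' Generate a synthetic spectra set with ground truth
#'
#' Per scan, the absorbance is
#' `(background + adsorbed * analyte + water_amp * water + contamination)
#'  * scatter + offset + tilt + noise`,
#' where `adsorbed = concentration * adsorptionFraction(ph) * volumeL /
#' massG` (mg analyte per g sorbent), `scatter ~ N(1, scatter_slope_sd)` is
#' drawn per scan, the water amplitude is drawn per extraction sample, and
#' the additive noise is heteroscedastic (extra sd outside 4068-9612 cm-1).
#' Everything is deterministic given `design$seed`.
#'
#' @param design a [studyDesign()].
#' @param components named component list as from [componentPresets()].
#' @param noise a [noiseModel()].
#' @param grid wavenumber grid (default [nirGrid()]).
#' @param idPrefix prefix for generated sample ids.
#' @param contamination optional list describing residual interferent
#'   carry-over: `component` (a `component_spectrum`),
#'   `amplitude_range` (`[low, high]`, drawn per sample) and optional
#'   `extra_scatter_sd` added to the scatter spread (the glucose mechanism).
#' @return A list with `spectra` (a [SpectraSet-class], one column per
#'   scan) and `truth` (data.frame with per-scan `sample_id`,
#'   `replicate_group`, `scan`, `concentration`, `adsorbed_mg_g`,
#'   `water_amplitude`, `scatter`, `contamination_amplitude`).
#' @export
generateSpectraSet <- function(design, components = componentPresets(),
                               noise = noiseModel(), grid = nirGrid(),
                               idPrefix = "S", contamination = NULL) {
  frac <- adsorptionFraction(design$ph)
  background <- gaussianSpectrum(components$sorbent, grid)
  analyte <- gaussianSpectrum(components$analyte, grid)
  water <- gaussianSpectrum(components$water, grid)
  contamSpec <- if (!is.null(contamination))
    gaussianSpectrum(contamination$component, grid) else NULL
  scatterSd <- noise$scatter_slope_sd +
    if (!is.null(contamination) && !is.null(contamination$extra_scatter_sd))
      contamination$extra_scatter_sd else 0
  edge <- grid < 4068 | grid > 9612
  tilt <- seq(-0.5, 0.5, length.out = length(grid))
  nSamp <- length(design$concentrations)
  nScan <- design$scansPerSample
  absmat <- matrix(NA_real_, nSamp * nScan, length(grid))
  truth <- data.frame(
    sample_id = character(nSamp * nScan), replicate_group = "",
    scan = 0L, concentration = 0, adsorbed_mg_g = 0,
    water_amplitude = 0, scatter = 0, contamination_amplitude = 0,
    stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(nSamp)) {
    conc <- design$concentrations[i]
    adsorbed <- conc * frac * design$volumeL / design$massG
    perSample <- .with_substream(design$seed, i * 1000L, {
      wrange <- noise$water_amplitude_range
      list(water_amp = stats::runif(1, wrange[1L], wrange[2L]),
           contam_amp = if (is.null(contamination)) 0 else
             stats::runif(1, contamination$amplitude_range[1L],
                          contamination$amplitude_range[2L]))
    })
    clean <- background + adsorbed * analyte +
      perSample$water_amp * water +
      perSample$contam_amp * (if (is.null(contamSpec)) 0 else contamSpec)
    for (k in seq_len(nScan)) {
      row <- row + 1L
      draws <- .with_substream(design$seed, i * 1000L + k, {
        list(scatter = 1 + stats::rnorm(1, 0, 1) * scatterSd,
             offset = stats::rnorm(1, 0, 1) * noise$baseline_offset_sd,
             tiltAmp = stats::rnorm(1, 0, 1) * noise$baseline_tilt_sd,
             eps = stats::rnorm(length(grid), 0, 1) * noise$additive_sd,
             epsEdge = stats::rnorm(length(grid), 0, 1) * noise$edge_noise_sd)
      })
      scatter <- max(draws$scatter, 0.2)  # physical lower bound
      spec <- clean * scatter + draws$offset + draws$tiltAmp * tilt +
        draws$eps + draws$epsEdge * edge
      absmat[row, ] <- spec
      truth$sample_id[row] <- sprintf("%s%02d_sc%d", idPrefix, i, k)
      truth$replicate_group[row] <- sprintf("%s%02d", idPrefix, i)
      truth$scan[row] <- k
      truth$concentration[row] <- conc
      truth$adsorbed_mg_g[row] <- adsorbed
      truth$water_amplitude[row] <- perSample$water_amp
      truth$scatter[row] <- scatter
      truth$contamination_amplitude[row] <- perSample$contam_amp
    }
  }
  meta <- data.frame(sample_id = truth$sample_id,
                     concentration = truth$concentration,
                     replicate_group = truth$replicate_group,
                     role = design$role, stringsAsFactors = FALSE)
  list(spectra = SpectraSet(absmat, grid, meta), truth = truth)
}

#' Generate the validation study bundle
#'
#' Builds the repeatability set (10 extractions of a 150 mg L-1 standard,
#' 3 scans each) and the selectivity sets: an unspiked control plus
#' ascorbic acid, tyrosine and glucose spikes.  At extraction pH 3.5,
#' ascorbic acid and tyrosine do not bind the sorbent and are washed away,
#' so their sets are generated with no interference mechanism; glucose is
#' partly retained in the resin, modeled as residual spectral contamination
#' plus extra scatter spread (sticky, non-uniform particles).
#'
#' @param seed integer seed.
#' @param nominal standard concentration, mg L-1 (default 150).
#' @param n extractions per condition (default 10).
#' @param noise a [noiseModel()].
#' @param glucoseAmplitudeRange contamination amplitude range for the
#'   glucose set.
#' @param glucoseExtraScatterSd extra scatter sd for the glucose set.
#' @return A list with elements `repeatability` and `selectivity` (a named
#'   list `control`, `ascorbic`, `tyrosine`, `glucose`), each a
#'   `list(spectra, truth)` as returned by [generateSpectraSet()], plus
#'   `nominal`.
#' @export
generateValidationSuite <- function(seed, nominal = 150, n = 10L,
                                    noise = noiseModel(),
                                    glucoseAmplitudeRange = c(0.02, 0.10),
                                    glucoseExtraScatterSd = 0.04) {
  mkDesign <- function(offset)
    studyDesign(concentrations = rep(nominal, n), role = "validation",
                seed = seed + offset)
  presets <- componentPresets()
  glucose <- list(component = presets$glucose,
                  amplitude_range = glucoseAmplitudeRange,
                  extra_scatter_sd = glucoseExtraScatterSd)
  list(
    repeatability = generateSpectraSet(mkDesign(101L), noise = noise,
                                       idPrefix = "R"),
    selectivity = list(
      control = generateSpectraSet(mkDesign(211L), noise = noise,
                                   idPrefix = "C"),
      ascorbic = generateSpectraSet(mkDesign(223L), noise = noise,
                                    idPrefix = "A"),
      tyrosine = generateSpectraSet(mkDesign(227L), noise = noise,
                                    idPrefix = "T"),
      glucose = generateSpectraSet(mkDesign(229L), noise = noise,
                                   idPrefix = "G", contamination = glucose)
    ),
    nominal = nominal
  )
}
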