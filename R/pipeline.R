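## End-to-end workflow: load (or simulate) -> pretreat -> average replicates
## -> fit + cross-validate -> figures of merit -> report files.
##
## The stage order is fixed: replicate scans are averaged AFTER pretreatment
## and before model fitting; the configuration cannot reorder this.

#' Default pipeline configuration
#'
#' Returns the configuration list used by [runCalibration()].  Fields:
#' `input` (`list(spectra, meta)` CSV paths, or `NULL` to simulate),
#' `simulate` (`list(enabled, concentrations, scans_per_sample, ph)`),
#' `regions` (kept intervals, cm-1), `plan` (preset name or step list),
#' `max_factors`, `cv` (`"loo"` or a segment count), `ratio`
#' (factor-selection tolerance), `var_x` (`"residual"` or a number),
#' `seed`, and `output_dir` (`NULL` writes no files).
#'
#' @return A named list.
#' @export
defaultConfig <- function() {
  list(
    input = NULL,
    simulate = list(enabled = TRUE,
                    concentrations = rep(seq(0, 300, by = 25), each = 4),
                    scans_per_sample = 3L, ph = 3.5),
    regions = defaultRegions(),
    plan = "reference",
    max_factors = 10L,
    cv = "loo",
    ratio = 1,
    var_x = "residual",
    seed = 1L,
    output_dir = NULL
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `readPipelineConfig()` returns the configuration list (defaults
#'   filled in for missing fields).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultConfig()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (!is.null(base$regions) && !is.matrix(base$regions))
    base$regions <- do.call(rbind, lapply(base$regions, as.numeric))
  if (is.list(base$plan)) base$plan <- .plan_from_list(base$plan)
  base
}

#' @rdname readPipelineConfig
#' @param config a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  if (is.matrix(config$regions))
    config$regions <- lapply(seq_len(nrow(config$regions)),
                             function(i) as.numeric(config$regions[i, ]))
  if (inherits(config$plan, "preprocess_plan"))
    config$plan <- .plan_to_list(config$plan)
  yaml::write_yaml(config, path)
  invisible(NULL)
}

.resolve_plan <- function(config) {
  if (inherits(config$plan, "preprocess_plan")) config$plan
  else if (is.character(config$plan))
    preprocessPlan(config$plan, regions = config$regions)
  else if (is.list(config$plan)) .plan_from_list(config$plan)
  else stop("config error: plan must be a preset name or a step list")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' Run the calibration pipeline
#'
#' Executes load (or simulate) -> pretreatment plan -> replicate averaging
#' -> NIPALS PLS1 fit with cross-validation -> figures of merit, and
#' optionally writes a report directory (`report.txt`, `metrics.csv`,
#' `fom.csv`, `model.json`, `config.yaml`).  The run is deterministic given
#' the configuration and seed; report files carry no timestamps.
#'
#' @param config configuration list (see [defaultConfig()]) or a YAML path.
#' @return Invisibly, a list (`run_report`) with elements `model`
#'   ([PLSModel-class]), `metrics` ([CalibrationMetrics-class]), `fom`
#'   ([FiguresOfMerit-class]), `calibration` (the pretreated, averaged
#'   [SpectraSet-class]), `truth` (simulation ground truth or `NULL`) and
#'   `provenance`.
#' @export
runCalibration <- function(config = defaultConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  raw <- truth <- NULL
  if (!is.null(config$input)) {
    raw <- .stage("load",
      readSpectra(config$input$spectra, config$input$meta))
  } else if (isTRUE(config$simulate$enabled)) {
    sim <- .stage("simulate", {
      design <- studyDesign(
        concentrations = config$simulate$concentrations,
        scansPerSample = config$simulate$scans_per_sample,
        ph = config$simulate$ph, seed = config$seed)
      generateSpectraSet(design)
    })
    raw <- sim$spectra
    truth <- sim$truth
  } else stop("load stage: no input files and simulation disabled")
  plan <- .stage("preprocess", .resolve_plan(config))
  pre <- .stage("preprocess", applyPlan(raw, plan))
  avg <- .stage("average", averageReplicates(pre))
  metrics <- .stage("calibrate", {
    segments <- if (identical(config$cv, "loo")) NULL
      else .make_segments(sum(sampleMeta(avg)$role == "calibration"),
                          as.integer(config$cv), config$seed)
    crossValidate(avg, maxFactors = config$max_factors,
                  ratio = config$ratio, segments = segments)
  })
  model <- .stage("calibrate",
    fitCalibration(avg, maxFactors = chosenFactors(metrics)))
  fom <- .stage("fom", {
    varX <- if (identical(config$var_x, "residual")) NULL
            else as.numeric(config$var_x)
    computeFom(model, avg, varX = varX)
  })
  report <- list(model = model, metrics = metrics, fom = fom,
                 calibration = avg, truth = truth,
                 provenance = list(seed = config$seed,
                                   package = "tpcNIR",
                                   version = as.character(
                                     utils::packageVersion("tpcNIR"))))
  class(report) <- "run_report"
  if (!is.null(config$output_dir))
    .stage("report", .write_report(report, config, config$output_dir))
  invisible(report)
}

.make_segments <- function(n, k, seed) {
  idx <- .with_substream(seed, 777L, sample.int(n))
  split(idx, rep(seq_len(k), length.out = n))
}

.write_report <- function(report, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metricsTable(report$metrics),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$fom),
                   file.path(dir, "fom.csv"), row.names = FALSE)
  writePLSModel(report$model, file.path(dir, "model.json"))
  writePipelineConfig(config, file.path(dir, "config.yaml"))
  a <- chosenFactors(report$metrics)
  tab <- metricsTable(report$metrics)
  row <- tab[tab$factors == a, ]
  fom <- report$fom
  lines <- c(
    "tpcNIR calibration report",
    sprintf("package version: %s; seed: %s",
            report$provenance$version, report$provenance$seed),
    sprintf("calibration points: %d", nrow(report$model@scores)),
    sprintf("chosen factors: %d", a),
    sprintf("RMSEC: %.4f  R2cal: %.6f", row$rmsec, row$r2cal),
    sprintf("RMSEV: %.4f  R2val: %.6f", row$rmsev, row$r2val),
    sprintf("SEN: %.6g  var(x): %.6g  var(y_cal): %.6g",
            fom@sen, fom@varX, fom@varYcal),
    sprintf("h0: %.6g to %.6g", fom@h0Min, fom@h0Max),
    sprintf("LOD: %.1f to %.1f mg L-1", fom@lodMin, fom@lodMax),
    sprintf("LOQ: %.1f to %.1f mg L-1", fom@loqMin, fom@loqMax),
    sprintf("working range: %.1f to %.1f mg L-1",
            fom@workingRange[1L], fom@workingRange[2L]))
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(NULL)
}

#' Predict unknowns with a serialized or in-memory model
#'
#' Applies the pretreatment plan, averages replicate scans, predicts with
#' the model, and reports per replicate group the mean prediction, its sd
#' across scans (scan-level predictions before averaging), and the
#' dilution-corrected content when a `dilution` column is present in the
#' metadata (reported content = prediction x dilution factor).
#'
#' @param model a [PLSModel-class] or path to a serialized model JSON.
#' @param spectra a [SpectraSet-class] or a spectra CSV path.
#' @param meta metadata CSV path (when `spectra` is a path).
#' @param plan pretreatment plan or preset name (default `"reference"`,
#'   matching the calibration workflow).
#' @param regions regions for the plan's reduce step.
#' @param dilution optional numeric vector of dilution factors, one per
#'   replicate group (or a single factor recycled).
#' @return data.frame with `sample_id`, `n_scans`, `predicted`,
#'   `predicted_sd`, `dilution`, `content` (= predicted x dilution).
#' @export
runPredict <- function(model, spectra, meta = NULL, plan = "reference",
                       regions = defaultRegions(), dilution = 1) {
  if (is.character(model)) model <- readPLSModel(model)
  if (is.character(spectra)) spectra <- readSpectra(spectra, meta)
  if (is.character(plan)) plan <- preprocessPlan(plan, regions = regions)
  pre <- applyPlan(spectra, plan)
  scanPred <- predict(model, pre)              # per-scan predictions
  avg <- averageReplicates(pre)
  avgPred <- predict(model, avg)               # prediction of averaged spectra
  groups <- sampleMeta(avg)$sample_id
  scanGroups <- sampleMeta(pre)$replicate_group
  sds <- vapply(groups, function(g) {
    v <- scanPred[scanGroups == g]
    if (length(v) > 1L) stats::sd(v) else NA_real_
  }, 0)
  dil <- rep_len(dilution, length(groups))
  data.frame(sample_id = groups,
             n_scans = as.integer(table(factor(scanGroups, levels = groups))),
             predicted = avgPred, predicted_sd = sds,
             dilution = dil, content = avgPred * dil,
             row.names = NULL, stringsAsFactors = FALSE)
}
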