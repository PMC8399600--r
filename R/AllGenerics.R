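#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname sampleMeta
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname concentrations
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname reduceRegions
#' @export
setGeneric("reduceRegions", function(x, regions) standardGeneric("reduceRegions"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates", function(x) standardGeneric("averageReplicates"))

#' @rdname snv
#' @export
setGeneric("snv", function(x) standardGeneric("snv"))

#' @rdname msc
#' @export
setGeneric("msc", function(x, reference = NULL) standardGeneric("msc"))

#' @rdname detrendSpectra
#' @export
setGeneric("detrendSpectra", function(x, degree = 1L) standardGeneric("detrendSpectra"))

#' @rdname sgFilter
#' @export
setGeneric("sgFilter", function(x, window, polyorder, derivorder = 0L)
  standardGeneric("sgFilter"))

#' @rdname applyPlan
#' @export
setGeneric("applyPlan", function(x, plan) standardGeneric("applyPlan"))

#' @rdname crossValidate
#' @export
setGeneric("crossValidate", function(x, ...) standardGeneric("crossValidate"))

#' @rdname metricsTable
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname metricsTable
#' @export
setGeneric("chosenFactors", function(x) standardGeneric("chosenFactors"))

#' @rdname computeFom
#' @export
setGeneric("computeFom", function(model, calibration, ...)
  standardGeneric("computeFom"))

#' @rdname computeFom
#' @export
setGeneric("workingRange", function(x) standardGeneric("workingRange"))
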