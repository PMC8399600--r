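## SpectraSet construction, validity, accessors, I/O, region selection and
## replicate averaging.

.SAMPLE_ROLES <- c("calibration", "validation", "blank", "unknown")

.check_grid <- function(wn) {
  if (length(wn) == 0L) return("grid error: empty wavenumber grid")
  if (any(!is.finite(wn))) return("grid error: non-finite wavenumbers")
  if (min(wn) < 4000 - 1e-6 || max(wn) > 10000 + 1e-6)
    return("grid error: wavenumbers must lie within [4000, 10000] cm-1")
  if (length(wn) >= 2L) {
    d <- diff(wn)
    if (any(d >= 0))
      return("grid error: wavenumbers must be strictly descending")
    ## uniform base spacing; region-reduced grids may carry gaps that are
    ## integer multiples of it
    base <- max(d)  # smallest magnitude (d < 0)
    mult <- d / base
    if (any(abs(mult - round(mult)) > 1e-9 * abs(mult)))
      return("grid error: non-uniform wavenumber spacing")
  }
  NULL
}

.check_meta <- function(meta) {
  need <- c("sample_id", "concentration", "replicate_group", "role")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    return(paste("format error: metadata lacks columns:",
                 paste(miss, collapse = ", ")))
  if (any(!meta$role %in% .SAMPLE_ROLES))
    return(paste("format error: role must be one of",
                 paste(.SAMPLE_ROLES, collapse = ", ")))
  conc <- meta$concentration
  if (any(!is.na(conc) & conc < 0))
    return("format error: concentrations must be non-negative")
  if (any(meta$role == "calibration" & is.na(conc)))
    return("format error: calibration samples require a concentration")
  NULL
}

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    return("SpectraSet requires an 'absorbance' assay")
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (any(!is.finite(a)))
    msg <- c(msg, "all absorbances must be finite")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn))
    msg <- c(msg, "rowData must carry a 'wavenumber' column")
  else {
    g <- .check_grid(wn)
    if (!is.null(g)) msg <- c(msg, g)
  }
  meta <- as.data.frame(SummarizedExperiment::colData(object))
  m <- .check_meta(meta)
  if (!is.null(m)) msg <- c(msg, m)
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples x wavenumbers (the orientation
#'   used in spectra CSV files; it is transposed internally to the
#'   wavenumber x sample SummarizedExperiment layout).
#' @param wavenumbers numeric vector of wavenumbers in cm-1, strictly
#'   descending with uniform spacing, one per column of `absorbance`.
#' @param meta data.frame with columns `sample_id`, `concentration`,
#'   `replicate_group`, `role`; one row per row of `absorbance`.
#' @return A validated [SpectraSet-class] object.
#' @examples
#' wn <- seq(5000, 4968, by = -8)
#' abs <- matrix(runif(15), 3, 5)
#' meta <- data.frame(sample_id = c("a", "b", "c"),
#'                    concentration = c(0, 100, 200),
#'                    replicate_group = c("a", "b", "c"),
#'                    role = "calibration")
#' s <- SpectraSet(abs, wn, meta)
#' dim(spectraMatrix(s))
#' @export
SpectraSet <- function(absorbance, wavenumbers, meta) {
  absorbance <- as.matrix(absorbance)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(absorbance) != nrow(meta))
    stop("format error: ", nrow(absorbance), " spectra but ",
         nrow(meta), " metadata rows")
  if (ncol(absorbance) != length(wavenumbers))
    stop("format error: ", ncol(absorbance), " columns but ",
         length(wavenumbers), " wavenumbers")
  if (!is.numeric(absorbance))
    stop("format error: non-numeric absorbance values")
  g <- .check_grid(wavenumbers)
  if (!is.null(g)) stop(g)
  m <- .check_meta(meta)
  if (!is.null(m)) stop(m)
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate_group <- as.character(meta$replicate_group)
  meta$concentration <- as.numeric(meta$concentration)
  assay <- t(absorbance)
  dimnames(assay) <- list(NULL, if (nrow(meta)) meta$sample_id else NULL)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = assay),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(meta, row.names = NULL)
  )
  methods::validObject(obj <- methods::new("SpectraSet", se))
  obj
}

#' Wavenumber grid of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return Numeric vector of wavenumbers in cm-1 (descending).
#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' Grid spacing in cm-1
#'
#' Signed step between consecutive stored wavenumbers (negative on the
#' descending instrument grid).
#' @param x a [SpectraSet-class].
#' @export
gridSpacing <- function(x) {
  wn <- wavenumbers(x)
  if (length(wn) < 2L) stop("grid error: spacing undefined for a single point")
  max(diff(wn))  # signed base step (smallest magnitude; diffs are negative)
}

#' Absorbance matrix in samples x wavenumbers orientation
#'
#' @param x a [SpectraSet-class].
#' @return Numeric matrix, one row per spectrum, one column per wavenumber.
#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x)
  t(SummarizedExperiment::assay(x, "absorbance")))

#' Sample metadata as a data.frame
#'
#' @param x a [SpectraSet-class].
#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "SpectraSet", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  rownames(df) <- NULL
  df
})

#' Reference concentrations (mg L-1 GAE)
#'
#' @param x a [SpectraSet-class].
#' @rdname concentrations
#' @export
setMethod("concentrations", "SpectraSet", function(x)
  as.numeric(SummarizedExperiment::colData(x)$concentration))

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat("SpectraSet with", ncol(object), "spectra x", nrow(object),
      "wavenumbers\n")
  if (length(wn))
    cat(sprintf("  grid: %.0f to %.0f cm-1 (step %.3g)\n",
                wn[1L], wn[length(wn)],
                if (length(wn) > 1L) wn[2L] - wn[1L] else NA_real_))
  roles <- table(SummarizedExperiment::colData(object)$role)
  if (length(roles))
    cat("  roles:", paste(names(roles), roles, sep = ":", collapse = " "), "\n")
})

## ---- I/O ------------------------------------------------------------------

#' Read a SpectraSet from a pair of CSV files
#'
#' The spectra CSV has a `sample_id` first column and one column per
#' wavenumber (header = wavenumber in cm-1); the metadata CSV has columns
#' `sample_id`, `concentration` (empty for unknown), `replicate_group`,
#' `role`.  Sample order must agree between the two files.
#'
#' @param spectraPath,metaPath paths to the two CSV files.
#' @return A validated [SpectraSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(spectraPath, metaPath) {
  sp <- utils::read.csv(spectraPath, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!ncol(sp) || colnames(sp)[1L] != "sample_id")
    stop("format error: spectra CSV must start with a 'sample_id' column")
  wn <- suppressWarnings(as.numeric(colnames(sp)[-1L]))
  if (any(is.na(wn)))
    stop("format error: non-numeric wavenumber header in spectra CSV")
  absmat <- as.matrix(sp[, -1L, drop = FALSE])
  if (nrow(absmat) == 0L)
    absmat <- matrix(numeric(), 0L, length(wn))
  if (!is.numeric(absmat) || anyNA(absmat))
    stop("format error: non-numeric absorbance values in spectra CSV")
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(sp))
    stop("format error: ", nrow(sp), " spectra rows but ",
         nrow(meta), " metadata rows")
  if (nrow(meta) && any(as.character(meta$sample_id) != as.character(sp$sample_id)))
    stop("format error: sample_id order differs between spectra and metadata")
  if ("concentration" %in% names(meta))
    meta$concentration <- suppressWarnings(as.numeric(meta$concentration))
  SpectraSet(absmat, wn, meta)
}

#' Write a SpectraSet to a pair of CSV files
#'
#' Inverse of [readSpectra()]: `readSpectra()` on the written files
#' reproduces the set to within 1e-12 relative tolerance.
#'
#' @param x a [SpectraSet-class].
#' @param spectraPath,metaPath output CSV paths.
#' @export
writeSpectra <- function(x, spectraPath, metaPath) {
  stopifnot(methods::is(x, "SpectraSet"))
  meta <- sampleMeta(x)
  absmat <- spectraMatrix(x)
  df <- data.frame(sample_id = meta$sample_id, stringsAsFactors = FALSE)
  vals <- as.data.frame(format(absmat, digits = 17, trim = TRUE,
                               scientific = TRUE))
  if (nrow(absmat) == 0L)
    vals <- as.data.frame(matrix(character(), 0L, ncol(absmat)))
  colnames(vals) <- format(wavenumbers(x), digits = 15, trim = TRUE)
  out <- cbind(df, vals)
  utils::write.csv(out, spectraPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta[, c("sample_id", "concentration",
                            "replicate_group", "role")],
                   metaPath, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

## ---- region selection and replicate averaging -----------------------------

#' Model-building wavenumber regions
#'
#' The default retained regions for model building: 5344--9612 and
#' 4068--4960 cm-1.  This keeps the analyte-correlated bands while excluding
#' the residual-water OH-stretch region (4960--5344 cm-1) and the noisy
#' spectral ends (4000--4068 and 9612--10000 cm-1).
#'
#' @return A 2-column matrix of `[low, high]` closed intervals in cm-1.
#' @export
defaultRegions <- function() {
  m <- rbind(c(5344, 9612), c(4068, 4960))
  colnames(m) <- c("low", "high")
  m
}

.check_regions <- function(regions) {
  regions <- as.matrix(regions)
  if (ncol(regions) != 2L)
    stop("region error: regions must be a 2-column [low, high] matrix")
  if (any(regions[, 1L] >= regions[, 2L]))
    stop("region error: each interval requires low < high")
  o <- order(regions[, 1L])
  r <- regions[o, , drop = FALSE]
  if (nrow(r) > 1L && any(r[-1L, 1L] <= r[-nrow(r), 2L]))
    stop("region error: intervals must be non-overlapping")
  regions
}

#' Restrict a SpectraSet to retained wavenumber regions
#'
#' Keeps exactly the columns whose wavenumber lies inside any of the closed
#' `[low, high]` intervals; the original column order is preserved.
#' Applying the same region specification twice is idempotent.
#'
#' @param x a [SpectraSet-class].
#' @param regions 2-column matrix of closed intervals in cm-1, e.g.
#'   [defaultRegions()].
#' @return The reduced [SpectraSet-class].
#' @rdname reduceRegions
#' @export
setMethod("reduceRegions", "SpectraSet", function(x, regions) {
  regions <- .check_regions(regions)
  wn <- wavenumbers(x)
  keep <- rep(FALSE, length(wn))
  for (i in seq_len(nrow(regions)))
    keep <- keep | (wn >= regions[i, 1L] & wn <= regions[i, 2L])
  if (!any(keep))
    stop("region error: no wavenumbers fall inside the requested regions")
  x[keep, ]
})

#' Average replicate scans
#'
#' Collapses the set to one spectrum per `replicate_group` (arithmetic mean
#' of the member rows), in order of first appearance.  All members of a
#' group must share the same concentration and role.  In the standard
#' workflow averaging is applied after pretreatment.
#'
#' @param x a [SpectraSet-class].
#' @return A [SpectraSet-class] with one spectrum per replicate group; its
#'   `sample_id` is the group name.
#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectraSet", function(x) {
  meta <- sampleMeta(x)
  if (any(is.na(meta$replicate_group)) || any(meta$replicate_group == ""))
    stop("metadata error: replicate_group must be populated")
  groups <- unique(meta$replicate_group)
  absmat <- spectraMatrix(x)
  out <- matrix(NA_real_, length(groups), ncol(absmat))
  newmeta <- data.frame(sample_id = groups,
                        concentration = NA_real_,
                        replicate_group = groups,
                        role = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    idx <- which(meta$replicate_group == groups[i])
    conc <- unique(meta$concentration[idx])
    if (length(conc) > 1L && (any(is.na(conc)) || diff(range(conc)) > 0))
      stop("metadata error: conflicting concentrations within replicate group '",
           groups[i], "'")
    role <- unique(meta$role[idx])
    if (length(role) > 1L)
      stop("metadata error: conflicting roles within replicate group '",
           groups[i], "'")
    out[i, ] <- colMeans(absmat[idx, , drop = FALSE])
    newmeta$concentration[i] <- conc[1L]
    newmeta$role[i] <- role
  }
  SpectraSet(out, wavenumbers(x), newmeta)
})
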