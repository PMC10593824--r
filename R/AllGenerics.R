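#' Accessors for CEST data objects
#'
#' \code{offsets} returns the saturation offsets (ppm); \code{schedule} the
#' attached [OffsetSchedule-class]; \code{gridDim} the 3D spatial grid;
#' \code{validMask} the voxel validity mask; \code{shifts} the B0 shift array;
#' \code{fitParam} one named parameter plane of a [TwoPoolFit-class];
#' \code{metricMap} one named metric plane of a [MetricMaps-class].
#'
#' @param x the object.
#' @param name parameter / metric name (\code{fitParam}: one of
#'   \code{c, A_ds, d_ds, w_ds, A_mt, d_mt, w_mt}; \code{metricMap}: one of
#'   \code{LD, MTRasym, MTRrex}).
#' @return numeric vector or array; see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))

#' @rdname accessors
#' @export
setGeneric("fitParam", function(x, name) standardGeneric("fitParam"))

#' @rdname accessors
#' @export
setGeneric("metricMap", function(x, name) standardGeneric("metricMap"))

#' @rdname accessors
#' @export
setMethod("offsets", "OffsetSchedule", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("offsets", "RawCestVolume", function(x) x@schedule@offsets)

#' @rdname accessors
#' @export
setMethod("offsets", "ZSpectrumVolume", function(x) x@schedule@offsets)

#' @rdname accessors
#' @export
setMethod("schedule", "RawCestVolume", function(x) x@schedule)

#' @rdname accessors
#' @export
setMethod("schedule", "ZSpectrumVolume", function(x) x@schedule)

#' @rdname accessors
#' @export
setMethod("schedule", "TwoPoolFit", function(x) x@schedule)

#' @rdname accessors
#' @export
setMethod("gridDim", "RawCestVolume", function(x) dim(x@data)[1:3])

#' @rdname accessors
#' @export
setMethod("gridDim", "ZSpectrumVolume", function(x) dim(x@z)[1:3])

#' @rdname accessors
#' @export
setMethod("gridDim", "TwoPoolFit", function(x) dim(x@params)[1:3])

#' @rdname accessors
#' @export
setMethod("gridDim", "B0Map", function(x) dim(x@shift))

#' @rdname accessors
#' @export
setMethod("gridDim", "MetricMaps", function(x) dim(x@ldApt))

#' @rdname accessors
#' @export
setMethod("validMask", "ZSpectrumVolume", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("validMask", "B0Map", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "MetricMaps", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("shifts", "B0Map", function(x) x@shift)

#' @rdname accessors
#' @export
setMethod("fitParam", "TwoPoolFit", function(x, name) {
  name <- match.arg(name, TWO_POOL_PARAMS)
  i <- match(name, TWO_POOL_PARAMS)
  x@params[, , , i, drop = TRUE]
})

#' @rdname accessors
#' @export
setMethod("metricMap", "MetricMaps", function(x, name) {
  name <- match.arg(name, c("LD", "MTRasym", "MTRrex"))
  switch(name, LD = x@ldApt, MTRasym = x@mtrAsymApt, MTRrex = x@mtrRexApt)
})

setMethod("show", "OffsetSchedule", function(object) {
  off <- object@offsets
  cat(sprintf("OffsetSchedule: %d offsets in [%.4g, %.4g] ppm\n",
              length(off), min(off), max(off)))
  cat(sprintf("  reference: %d frame(s) at %.4g ppm, using %s\n",
              object@nReferenceImages, object@referenceOffset,
              if (is.na(object@referenceSelection)) "their mean"
              else sprintf("frame %d", object@referenceSelection)))
})

setMethod("show", "RawCestVolume", function(object) {
  d <- dim(object@data)
  p <- object@provenance
  cat(sprintf("RawCestVolume: %dx%dx%d grid, %d frames (%d reference)\n",
              d[1], d[2], d[3], d[4], object@schedule@nReferenceImages))
  if (length(p))
    cat(sprintf("  scan: participant %s, scanner %s, session %s, repeat %s\n",
                p$participant, p$scanner, p$session, p$repeat.))
})

setMethod("show", "ZSpectrumVolume", function(object) {
  d <- dim(object@z)
  cat(sprintf("ZSpectrumVolume: %dx%dx%d grid, %d offsets, %d valid voxels%s\n",
              d[1], d[2], d[3], d[4], sum(object@validMask),
              if (object@b0Corrected) " (B0-corrected)" else ""))
})

setMethod("show", "TwoPoolFit", function(object) {
  d <- gridDim(object)
  cat(sprintf("TwoPoolFit: %dx%dx%d grid, %d converged of %d fitted voxels\n",
              d[1], d[2], d[3], sum(object@converged, na.rm = TRUE),
              sum(object@nPointsUsed > 0)))
})

setMethod("show", "B0Map", function(object) {
  s <- object@shift[object@valid]
  cat(sprintf("B0Map: %s grid, %d valid voxels",
              paste(gridDim(object), collapse = "x"), sum(object@valid)))
  if (length(s)) cat(sprintf(", median shift %.3f ppm", stats::median(s)))
  cat("\n")
})

setMethod("show", "MetricMaps", function(object) {
  v <- object@valid
  cat(sprintf("MetricMaps at %+.1f ppm: %s grid, %d valid voxels\n",
              object@targetOffset, paste(gridDim(object), collapse = "x"), sum(v)))
  if (any(v))
    cat(sprintf("  median LD %.2f%%, MTRasym %.2f%%, MTRrex %.2f%%\n",
                stats::median(object@ldApt[v], na.rm = TRUE),
                stats::median(object@mtrAsymApt[v], na.rm = TRUE),
                stats::median(object@mtrRexApt[v], na.rm = TRUE)))
})

setMethod("show", "CestDataset", function(object) {
  cat(sprintf("CestDataset: %d scans, grid %s, tissues: %s\n",
              length(object@scans),
              paste(object@config$gridShape, collapse = "x"),
              paste(names(object@masks), collapse = ", ")))
  cat(sprintf("  design: %d participants x %d scanner(s) x %d session(s) x %d repeat(s) [%s], seed %d\n",
              object@config$design$participants, object@config$design$scanners,
              object@config$design$sessions, object@config$design$repeats,
              object@config$design$plan, object@config$seed))
})
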