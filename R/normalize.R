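#' Normalize saturated CEST images to Z-spectra
#'
#' Divides every saturation frame by the per-voxel reference intensity
#' \eqn{z(v, \Delta\omega) = S_{sat}(v, \Delta\omega) / S_{ref}(v)}.
#' The reference is, by default, the last of the reference frames (the
#' schedule's \code{referenceSelection}); passing \code{referenceSelection =
#' NA} averages all reference frames instead. Voxels whose reference
#' intensity falls at or below the intensity floor (a small fraction of the
#' volume's median intensity, guarding against division blow-ups in
#' background air) are flagged invalid, never raised as an error. The
#' operation is homogeneous: rescaling all intensities by a positive
#' constant leaves z unchanged.
#'
#' @param raw a [RawCestVolume-class].
#' @param referenceSelection overrides the schedule's reference-frame
#'   choice: a 1-based index among the reference frames, or \code{NA} for
#'   their mean.
#' @param floorFraction intensity floor as a fraction of the volume median
#'   intensity (default 1e-6).
#' @return a [ZSpectrumVolume-class]; invalid voxels carry NA spectra.
#' @export
#' @examples
#' sch <- buildOffsetSchedule(offsets = c(-3.5, 0, 3.5),
#'                            nReferenceImages = 1L)
#' arr <- array(1000, c(2, 2, 1, 4))
#' arr[, , , 2:4] <- 500
#' raw <- new("RawCestVolume", data = arr, schedule = sch,
#'            voxelSize = c(1, 1, 1), provenance = list())
#' normalizeZSpectra(raw)@z[1, 1, 1, ]  # 0.5 at every offset
normalizeZSpectra <- function(raw, referenceSelection = NULL,
                              floorFraction = 1e-6) {
  stopifnot(is(raw, "RawCestVolume"))
  sched <- raw@schedule
  sel <- if (is.null(referenceSelection)) sched@referenceSelection
         else as.integer(referenceSelection)
  refIdx <- referenceFrameIndices(sched)
  d <- dim(raw@data)
  sref <- if (is.na(sel)) {
    apply(raw@data[, , , refIdx, drop = FALSE], 1:3, mean)
  } else {
    if (sel < 1L || sel > sched@nReferenceImages)
      stop("referenceSelection out of range")
    array(raw@data[, , , refIdx[sel]], d[1:3])
  }
  floor <- floorFraction * stats::median(raw@data)
  valid <- is.finite(sref) & sref > floor
  nSat <- length(sched@offsets)
  z <- raw@data[, , , saturationFrameIndices(sched), drop = FALSE] /
    array(rep(sref, nSat), c(d[1:3], nSat))
  z[array(rep(!valid, nSat), c(d[1:3], nSat))] <- NA_real_
  new("ZSpectrumVolume", z = z, schedule = sched, validMask = valid,
      b0Corrected = FALSE)
}
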