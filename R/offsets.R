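#' Default saturation-offset sampling bands
#'
#' The acquisition scheme used throughout the package by default: 43 offsets
#' between -100 and 100 ppm, densely sampled around the water resonance
#' (+/-100 ppm; +/-50 to +/-10 in steps of 10; +/-9 to +/-5 in steps of 1;
#' +/-4.5 to +/-1 in steps of 0.5; -0.5 to 0.5 in steps of 0.25).
#'
#' @return list of \code{c(start, stop, step)} bands in ppm.
#' @export
#' @examples
#' length(offsets(buildOffsetSchedule()))  # 43
defaultOffsetBands <- function() {
  list(
    c(-100, -100, 1), c(100, 100, 1),
    c(-50, -10, 10), c(10, 50, 10),
    c(-9, -5, 1), c(5, 9, 1),
    c(-4.5, -1, 0.5), c(1, 4.5, 0.5),
    c(-0.5, 0.5, 0.25)
  )
}

#' Build a saturation-offset schedule
#'
#' Constructs an [OffsetSchedule-class] either from sampling bands
#' (\code{c(start, stop, step)} triplets, merged, sorted and de-duplicated)
#' or from an explicit offset vector. The default bands reproduce the
#' standard 43-offset scheme of [defaultOffsetBands()]. Offsets are
#' canonicalized to 0.01 ppm resolution; duplicates arising after merging
#' bands are removed with a warning. Schedules lacking +/-3.5 ppm are
#' rejected, as the APT analysis target would be unavailable.
#'
#' @param bands list of numeric \code{c(start, stop, step)} triplets.
#' @param offsets explicit numeric offsets (ppm); overrides \code{bands}.
#' @param referenceOffset placeholder offset (ppm) of the reference images.
#' @param nReferenceImages number of reference frames acquired per scan.
#' @param referenceSelection 1-based index of the reference frame used for
#'   normalization (default: the last one), or \code{NA} to use the mean of
#'   all reference frames.
#' @return an [OffsetSchedule-class].
#' @export
#' @examples
#' sch <- buildOffsetSchedule()
#' length(offsets(sch))                     # 43
#' sum(abs(offsets(sch)) <= 0.5)            # 5
#' buildOffsetSchedule(offsets = c(-3.5, 0, 3.5))
buildOffsetSchedule <- function(bands = defaultOffsetBands(),
                                offsets = NULL,
                                referenceOffset = -300,
                                nReferenceImages = 4L,
                                referenceSelection = nReferenceImages) {
  if (is.null(offsets)) {
    stopifnot(is.list(bands), all(vapply(bands, length, 1L) == 3L))
    offsets <- unlist(lapply(bands, function(b) {
      if (b[3] <= 0) stop("band step must be > 0")
      seq(b[1], b[2], by = b[3])
    }))
  }
  off <- round(as.numeric(offsets), OFFSET_RESOLUTION)
  dup <- duplicated(off)
  if (any(dup)) {
    warning(sprintf("%d duplicate offset(s) removed after merging bands", sum(dup)))
    off <- off[!dup]
  }
  off <- sort(off)
  new("OffsetSchedule",
      offsets            = off,
      referenceOffset    = as.numeric(referenceOffset),
      nReferenceImages   = as.integer(nReferenceImages),
      referenceSelection = as.integer(referenceSelection))
}

# Exact column index of an offset in the schedule (0.01 ppm resolution).
offsetIndex <- function(sched, target) {
  i <- match(round(target, OFFSET_RESOLUTION), sched@offsets)
  if (any(is.na(i)))
    stop(sprintf("offset(s) %s not in schedule",
                 paste(target[is.na(i)], collapse = ", ")))
  i
}

# 1-based positions of reference / saturation frames on the acquisition axis.
referenceFrameIndices <- function(sched) seq_len(sched@nReferenceImages)
saturationFrameIndices <- function(sched) {
  sched@nReferenceImages + seq_along(sched@offsets)
}
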