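#' @import methods
NULL

# Offsets are stored at 0.01 ppm resolution so that locating +/-3.5 ppm is an
# exact comparison, never a float-equality test.
OFFSET_RESOLUTION <- 2L

#' OffsetSchedule: saturation frequency offsets with reference bookkeeping
#'
#' Ordered saturation frequency offsets (ppm from water at 0) plus the
#' placeholder frequency and count of the unsaturated reference images
#' acquired with each CEST scan. Offsets are canonicalized to 0.01 ppm
#' resolution, sorted and de-duplicated. A schedule intended for APT-weighted
#' analysis must contain +3.5 and -3.5 ppm exactly.
#'
#' @slot offsets numeric, strictly increasing, all within [-100, 100] ppm.
#' @slot referenceOffset numeric(1), placeholder offset (ppm) of the
#'   reference images (far off-resonance).
#' @slot nReferenceImages integer(1), number of reference frames acquired.
#' @slot referenceSelection integer(1), index (1-based, among the reference
#'   frames) of the frame used for normalization, or \code{NA} to average all
#'   reference frames.
#'
#' @seealso [buildOffsetSchedule()]
#' @export
setClass("OffsetSchedule",
  representation(
    offsets            = "numeric",
    referenceOffset    = "numeric",
    nReferenceImages   = "integer",
    referenceSelection = "integer"
  )
)

setValidity("OffsetSchedule", function(object) {
  msg <- character()
  off <- object@offsets
  if (length(off) < 1L) msg <- c(msg, "schedule must contain at least one offset")
  if (any(!is.finite(off))) msg <- c(msg, "offsets must be finite")
  if (is.unsorted(off, strictly = TRUE)) msg <- c(msg, "offsets must be strictly sorted")
  if (any(off < -100 | off > 100)) msg <- c(msg, "offsets must lie within [-100, 100] ppm")
  if (!all(c(-3.5, 3.5) %in% off))
    msg <- c(msg, "schedule must contain +3.5 and -3.5 ppm (required for APT analysis)")
  if (object@nReferenceImages < 1L) msg <- c(msg, "nReferenceImages must be >= 1")
  rs <- object@referenceSelection
  if (!is.na(rs) && (rs < 1L || rs > object@nReferenceImages))
    msg <- c(msg, "referenceSelection out of range")
  if (length(msg)) msg else TRUE
})

#' RawCestVolume: acquired saturation-image series
#'
#' A 4D intensity array (three spatial axes by acquisition frame) together
#' with its offset schedule, voxel size and scan provenance. The acquisition
#' axis holds the reference frames first (\code{nReferenceImages} of them,
#' acquired at the placeholder offset), followed by one frame per scheduled
#' saturation offset, in schedule order.
#'
#' @slot data 4D non-negative numeric array.
#' @slot schedule an [OffsetSchedule-class].
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot provenance list with elements \code{participant}, \code{scanner},
#'   \code{session}, \code{repeat.} identifying the scan.
#' @export
setClass("RawCestVolume",
  representation(
    data       = "array",
    schedule   = "OffsetSchedule",
    voxelSize  = "numeric",
    provenance = "list"
  )
)

setValidity("RawCestVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array")
  nExpected <- length(object@schedule@offsets) + object@schedule@nReferenceImages
  if (length(d) == 4L && d[4L] != nExpected)
    msg <- c(msg, sprintf("acquisition axis has %d frames, expected %d (offsets + references)",
                          d[4L], nExpected))
  if (any(object@data < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' ZSpectrumVolume: per-voxel normalized Z-spectra
#'
#' Normalized saturation signal S_sat/S_ref per voxel and scheduled offset.
#' The fourth array axis is aligned with \code{offsets(schedule)}. Voxels
#' whose reference intensity fell below the intensity floor are flagged
#' invalid; individual offsets lost during B0 resampling are \code{NA}.
#'
#' @slot z 4D numeric array (3 spatial axes x offset).
#' @slot schedule an [OffsetSchedule-class].
#' @slot validMask logical 3D array, TRUE where the voxel is usable.
#' @slot b0Corrected logical(1), whether B0 resampling was already applied.
#' @export
setClass("ZSpectrumVolume",
  representation(
    z           = "array",
    schedule    = "OffsetSchedule",
    validMask   = "array",
    b0Corrected = "logical"
  ),
  prototype(b0Corrected = FALSE)
)

setValidity("ZSpectrumVolume", function(object) {
  msg <- character()
  d <- dim(object@z)
  if (length(d) != 4L) msg <- c(msg, "z must be a 4D array")
  if (length(d) == 4L && d[4L] != length(object@schedule@offsets))
    msg <- c(msg, "offset axis does not match the schedule")
  if (!identical(dim(object@validMask), d[1:3]))
    msg <- c(msg, "validMask must match the spatial grid")
  vm <- object@validMask
  if (any(object@z[rep(as.vector(vm), d[4L])] < 0, na.rm = TRUE))
    msg <- c(msg, "z must be >= 0 wherever valid")
  if (length(msg)) msg else TRUE
})

# Parameter plane order of the two-pool fit arrays.
TWO_POOL_PARAMS <- c("c", "A_ds", "d_ds", "w_ds", "A_mt", "d_mt", "w_mt")

#' TwoPoolFit: voxelwise DS + MT Lorentzian fit results
#'
#' Per-voxel parameters of the two-pool model
#' \eqn{\hat z(\Delta\omega) = c - L_{ds}(\Delta\omega) - L_{mt}(\Delta\omega)}
#' fitted by bounded nonlinear least squares, with residual norms,
#' convergence flags and the number of spectral points used.
#'
#' @slot params 4D array (3 spatial axes x 7), parameter planes in the order
#'   \code{c, A_ds, d_ds, w_ds, A_mt, d_mt, w_mt}.
#' @slot residualNorm 3D array, residual sum of squares of the fit.
#' @slot converged logical 3D array.
#' @slot nPointsUsed integer 3D array, offsets actually entering the fit.
#' @slot schedule the [OffsetSchedule-class] the fit was computed against.
#' @slot fitRegion logical vector over \code{offsets(schedule)} marking the
#'   offsets admitted to the fit.
#' @export
setClass("TwoPoolFit",
  representation(
    params       = "array",
    residualNorm = "array",
    converged    = "array",
    nPointsUsed  = "array",
    schedule     = "OffsetSchedule",
    fitRegion    = "logical"
  )
)

setValidity("TwoPoolFit", function(object) {
  msg <- character()
  d <- dim(object@params)
  if (length(d) != 4L || d[4L] != 7L) msg <- c(msg, "params must be a 4D array with 7 planes")
  for (nm in c("residualNorm", "converged", "nPointsUsed"))
    if (!identical(dim(slot(object, nm)), d[1:3]))
      msg <- c(msg, sprintf("%s must match the spatial grid", nm))
  if (length(object@fitRegion) != length(object@schedule@offsets))
    msg <- c(msg, "fitRegion must align with the schedule")
  if (length(msg)) msg else TRUE
})

#' B0Map: voxelwise static-field offset
#'
#' Per-voxel shift (ppm) of the fitted two-pool minimum from 0 ppm. Voxels
#' with |shift| beyond the acceptance range or a non-converged fit are
#' invalid.
#'
#' @slot shift 3D numeric array, ppm.
#' @slot valid logical 3D array.
#' @export
setClass("B0Map",
  representation(shift = "array", valid = "array")
)

setValidity("B0Map", function(object) {
  msg <- character()
  if (!identical(dim(object@shift), dim(object@valid)))
    msg <- c(msg, "shift and valid must share a grid")
  s <- object@shift[object@valid]
  if (any(abs(s) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "|shift| must be <= 1 ppm where valid")
  if (length(msg)) msg else TRUE
})

#' MetricMaps: APT-weighted metrics at +3.5 ppm
#'
#' Voxelwise Lorentzian difference (LD), magnetization transfer ratio
#' asymmetry (MTRasym) and inverse-difference (MTRrex) maps evaluated at the
#' target offset, in percent of the normalized signal. All three maps share
#' one validity mask.
#'
#' @slot ldApt 3D numeric array, percent.
#' @slot mtrAsymApt 3D numeric array, percent.
#' @slot mtrRexApt 3D numeric array, percent.
#' @slot valid logical 3D array.
#' @slot targetOffset numeric(1), ppm (default analysis target +3.5).
#' @export
setClass("MetricMaps",
  representation(
    ldApt        = "array",
    mtrAsymApt   = "array",
    mtrRexApt    = "array",
    valid        = "array",
    targetOffset = "numeric"
  )
)

setValidity("MetricMaps", function(object) {
  msg <- character()
  d <- dim(object@ldApt)
  for (nm in c("mtrAsymApt", "mtrRexApt", "valid"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("%s must match the grid of ldApt", nm))
  if (length(msg)) msg else TRUE
})

#' CestDataset: a synthetic multi-scan CEST study with ground truth
#'
#' The output of [generateDataset()]: one [RawCestVolume-class] per scan of
#' the reproducibility design, tissue masks on the common grid, the realized
#' ground-truth pool amplitudes per scan, the simulated B0 field, and the
#' generating configuration (including the seed).
#'
#' @slot scans list of [RawCestVolume-class], named by scan id.
#' @slot masks named list of logical 3D arrays (one per tissue label).
#' @slot truth data.frame of realized pool parameters per scan
#'   (see [truthSummary()]).
#' @slot b0Field 3D numeric array, simulated field offset in ppm.
#' @slot manifest data.frame with one row per scan (participant, scanner,
#'   session, repeat, scan id).
#' @slot config the validated phantom configuration list.
#' @export
setClass("CestDataset",
  representation(
    scans    = "list",
    masks    = "list",
    truth    = "data.frame",
    b0Field  = "array",
    manifest = "data.frame",
    config   = "list"
  )
)

setValidity("CestDataset", function(object) {
  msg <- character()
  if (length(object@scans) != nrow(object@manifest))
    msg <- c(msg, "manifest must have one row per scan")
  if (length(msg)) msg else TRUE
})
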