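#' APT-weighted metrics at +3.5 ppm
#'
#' Computes the three APT-weighted maps from a B0-corrected Z-spectrum
#' volume and its two-pool fit, in percent of the normalized signal:
#' \describe{
#'   \item{LD}{Lorentzian difference,
#'     \eqn{\hat z_{fit}(\Delta\omega) - z(\Delta\omega)} at the target:
#'     positive where a saturation dip exceeds the fitted DS + MT baseline.}
#'   \item{MTRasym}{asymmetry, \eqn{z(-\Delta\omega) - z(+\Delta\omega)}:
#'     conflates APT (positive) and NOE (negative) contributions.}
#'   \item{MTRrex}{inverse difference,
#'     \eqn{1/z(+\Delta\omega) - 1/\hat z_{fit}(+\Delta\omega)}: satisfies
#'     the pointwise identity MTRrex * z * zfit = LD (fractional units).}
#' }
#' Because the corrected spectrum was resampled at (nominal + shift), the
#' fitted curve is evaluated at (target + shift) per voxel — both sides of
#' the subtraction live in the corrected frame, which makes the metrics
#' exact on noiseless data. No T1/R1 scaling is applied to MTRrex: the
#' acquisition carries no T1 map, so compensation beyond the inverse
#' difference is not possible from these data.
#'
#' Validity: a voxel is valid when its reference was valid, its fit
#' converged, its B0 estimate was accepted and both z and the fitted curve
#' at the target are available; MTRrex additionally requires both to exceed
#' \code{zFloor} (guarding the inversion near the water line and in
#' artifacts; such voxels are NA and invalid).
#'
#' @param zvol the B0-corrected [ZSpectrumVolume-class].
#' @param fit the [TwoPoolFit-class] from the uncorrected spectra.
#' @param b0 the [B0Map-class] used for the correction.
#' @param target APT offset (ppm), default +3.5; both \code{+target} and
#'   \code{-target} must be in the schedule.
#' @param zFloor minimal normalized signal admitted to the MTRrex
#'   inversion, default 0.05.
#' @return a [MetricMaps-class] (percent units).
#' @export
computeMetricMaps <- function(zvol, fit, b0, target = 3.5, zFloor = 0.05) {
  stopifnot(is(zvol, "ZSpectrumVolume"), is(fit, "TwoPoolFit"), is(b0, "B0Map"))
  d <- gridDim(zvol)
  nv <- prod(d)
  sched <- zvol@schedule
  iPos <- offsetIndex(sched, target)
  iNeg <- offsetIndex(sched, -target)
  zmat <- matrix(zvol@z, nrow = nv)
  zPos <- zmat[, iPos]
  zNeg <- zmat[, iNeg]
  shift <- as.vector(b0@shift)
  shift[!as.vector(b0@valid)] <- 0
  zfitPos <- predictFitted(fit, matrix(target + shift, ncol = 1L))[, 1L]

  ld <- zfitPos - zPos
  asym <- zNeg - zPos
  rexOK <- is.finite(zPos) & is.finite(zfitPos) & zPos > zFloor & zfitPos > zFloor
  rex <- ifelse(rexOK, 1 / zPos - 1 / zfitPos, NA_real_)

  valid <- as.vector(zvol@validMask) & as.vector(fit@converged) &
    as.vector(b0@valid) & is.finite(ld) & is.finite(asym) & rexOK
  ld[!valid] <- NA_real_
  asym[!valid] <- NA_real_
  rex[!valid] <- NA_real_
  new("MetricMaps",
      ldApt = array(100 * ld, d),
      mtrAsymApt = array(100 * asym, d),
      mtrRexApt = array(100 * rex, d),
      valid = array(valid, d),
      targetOffset = target)
}

#' Lorentzian-difference spectrum of one voxel
#'
#' \eqn{LD(\Delta\omega) = \hat z_{fit}(\Delta\omega) - z(\Delta\omega)}
#' over all scheduled offsets (fractional units), for inspection of the
#' CEST/NOE peaks a fit leaves behind.
#'
#' @param z numeric Z-spectrum aligned with the schedule.
#' @param par named numeric(7) two-pool parameters.
#' @param sched an [OffsetSchedule-class].
#' @return numeric vector of LD values over \code{offsets(sched)}.
#' @export
ldSpectrum <- function(z, par, sched) {
  twoPoolModel(unname(par), sched@offsets) - z
}
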