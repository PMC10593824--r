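#' Derive the B0 inhomogeneity map from two-pool fits
#'
#' The per-voxel shift is the position (ppm) of the minimum of the fitted
#' two-pool curve, located on a dense offset grid and measured from 0 ppm.
#' Ties in the minimum are broken toward the smallest |shift|. Voxels with a
#' non-converged fit, or with |shift| beyond \code{maxShift}, are marked
#' invalid.
#'
#' @param fit a [TwoPoolFit-class].
#' @param gridStep search-grid resolution (ppm), default 0.01.
#' @param searchRange search interval (ppm), default \code{c(-2, 2)}.
#' @param maxShift largest |shift| accepted as physical (ppm), default 1.
#' @return a [B0Map-class].
#' @export
computeB0Map <- function(fit, gridStep = 0.01, searchRange = c(-2, 2),
                         maxShift = 1) {
  stopifnot(is(fit, "TwoPoolFit"))
  d <- gridDim(fit)
  nv <- prod(d)
  grid <- seq(searchRange[1], searchRange[2], by = gridStep)
  # evaluate in |grid|-ascending order so which.min's first hit is the
  # smallest |shift| among exact ties
  ord <- order(abs(grid), grid)
  gOrd <- grid[ord]
  shift <- rep(NA_real_, nv)
  fitted <- which(as.vector(fit@converged))
  if (length(fitted)) {
    curves <- predictFitted(fit, matrix(gOrd, nrow = nv, ncol = length(gOrd),
                                        byrow = TRUE))[fitted, , drop = FALSE]
    shift[fitted] <- gOrd[max.col(-curves, ties.method = "first")]
  }
  valid <- as.vector(fit@converged) & !is.na(shift) & abs(shift) <= maxShift
  shift[!valid] <- NA_real_
  new("B0Map", shift = array(shift, d), valid = array(valid, d))
}

#' Voxelwise B0 correction of a Z-spectrum volume
#'
#' Re-evaluates each voxel's spectrum at (nominal offsets + shift) by
#' piecewise-cubic (natural spline) interpolation of z against offset, so
#' that the corrected spectrum's water minimum sits at 0 ppm. Interpolated
#' values are clipped at 0 (z is non-negative by construction).
#' Offsets falling outside the sampled range after shifting become NA for
#' that voxel. Voxels with an invalid B0 estimate are passed through
#' unchanged (their shift is treated as 0 downstream). Applying the
#' correction twice with the same map does not undo or repeat it cleanly,
#' so a second application triggers a warning.
#'
#' @param zvol a [ZSpectrumVolume-class].
#' @param b0 a [B0Map-class] on the same grid.
#' @return a B0-corrected [ZSpectrumVolume-class].
#' @export
applyB0Correction <- function(zvol, b0) {
  stopifnot(is(zvol, "ZSpectrumVolume"), is(b0, "B0Map"))
  if (!identical(gridDim(zvol), gridDim(b0)))
    stop(sprintf("Z-spectrum grid %s does not match B0 grid %s",
                 paste(gridDim(zvol), collapse = "x"),
                 paste(gridDim(b0), collapse = "x")))
  if (zvol@b0Corrected)
    warning("spectrum volume is already B0-corrected; applying again")
  off <- zvol@schedule@offsets
  d <- gridDim(zvol)
  nv <- prod(d)
  zmat <- matrix(zvol@z, nrow = nv)
  out <- zmat
  shift <- as.vector(b0@shift)
  todo <- which(as.vector(zvol@validMask) & as.vector(b0@valid) & shift != 0)
  rng <- range(off)
  for (v in todo) {
    y <- zmat[v, ]
    okSrc <- is.finite(y)
    if (sum(okSrc) < 4L) next
    xi <- off + shift[v]
    inside <- xi >= max(rng[1], min(off[okSrc])) &
              xi <= min(rng[2], max(off[okSrc]))
    zi <- rep(NA_real_, length(off))
    if (any(inside))
      zi[inside] <- pmax(0, stats::spline(off[okSrc], y[okSrc],
                                          xout = xi[inside],
                                          method = "natural")$y)
    out[v, ] <- zi
  }
  new("ZSpectrumVolume", z = array(out, c(d, length(off))),
      schedule = zvol@schedule, validMask = zvol@validMask,
      b0Corrected = TRUE)
}
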