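#' Lorentzian saturation line
#'
#' The Lorentzian lineshape used for every saturation pool:
#' \deqn{L(\Delta\omega) = A \frac{(w/2)^2}{(w/2)^2 + (\Delta\omega - \delta)^2}}
#' symmetric about the pool center \eqn{\delta} with full width at half
#' maximum \eqn{w} and peak amplitude \eqn{A} (attained at
#' \eqn{\Delta\omega = \delta}).
#'
#' @param delta frequency offsets \eqn{\Delta\omega} (ppm), vectorized.
#' @param amplitude peak amplitude A (dimensionless fraction).
#' @param center pool center \eqn{\delta} (ppm).
#' @param fwhm full width at half maximum w (ppm), must be > 0.
#' @return numeric vector of saturation fractions.
#' @export
#' @examples
#' lorentzian(0, 0.8, 0, 2)      # 0.8 at the center
#' lorentzian(1, 0.8, 0, 2)      # 0.4 at center + fwhm/2
#' lorentzian(3, 0.8, 0, 2)      # 0.8/10
lorentzian <- function(delta, amplitude, center, fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be > 0")
  u <- (fwhm / 2)^2
  amplitude * u / (u + (delta - center)^2)
}

#' Evaluate the two-pool model curve
#'
#' \eqn{\hat z(\Delta\omega) = c - L_{ds}(\Delta\omega) - L_{mt}(\Delta\omega)}
#' for a parameter vector in the order
#' \code{c, A_ds, d_ds, w_ds, A_mt, d_mt, w_mt}.
#'
#' @param par numeric(7) parameter vector.
#' @param delta offsets (ppm).
#' @return model Z-spectrum values.
#' @export
twoPoolModel <- function(par, delta) {
  par[1L] -
    lorentzian(delta, par[2L], par[3L], par[4L]) -
    lorentzian(delta, par[5L], par[6L], par[7L])
}

# Analytic Jacobian of the residual (y - model) for nls.lm; rows = offsets,
# columns = c, A_ds, d_ds, w_ds, A_mt, d_mt, w_mt.
twoPoolResidJac <- function(par, delta, obs) {
  J <- matrix(0, length(delta), 7L)
  J[, 1L] <- -1
  for (k in c(0L, 3L)) {
    A <- par[2L + k]; d0 <- par[3L + k]; w <- par[4L + k]
    u <- (w / 2)^2
    dd <- delta - d0
    den <- u + dd^2
    J[, 2L + k] <- u / den                       # d r / d A  (= +S)
    J[, 3L + k] <- A * 2 * dd * u / den^2        # d r / d delta
    J[, 4L + k] <- A * dd^2 * (w / 2) / den^2    # d r / d w
  }
  J
}

#' Default fit-region predicate for two-pool fitting
#'
#' Admits offsets with |offset| <= \code{inner} ppm (the water line) or
#' |offset| >= \code{outer} ppm (the far wings and MT-dominated region),
#' excluding the intermediate band that carries the APT, amine and NOE peaks
#' so that the fitted DS + MT baseline passes over them and the Lorentzian
#' difference captures them.
#'
#' @param inner inner band half-width (ppm), default 1.25.
#' @param outer outer band start (ppm), default 8.
#' @return a predicate \code{function(offsets) -> logical}.
#' @export
defaultFitRegion <- function(inner = 1.25, outer = 8) {
  force(inner); force(outer)
  function(offsets) abs(offsets) <= inner | abs(offsets) >= outer
}

#' Default starting values and box bounds for the two-pool fit
#'
#' Initialization puts a narrow, near-complete direct-saturation (DS) line at
#' 0 ppm and a broad, weak semi-solid MT line at -1 ppm; the disjoint width
#' bounds (DS w in [0.3, 10] ppm, MT w in [10, 100] ppm) keep the two pools
#' from swapping roles. The baseline c is fitted within [0.8, 1.2]; DS center
#' is restricted to [-1, 1] ppm and MT center to [-3, 1] ppm.
#'
#' @return list with numeric(7) elements \code{start}, \code{lower},
#'   \code{upper} in parameter order \code{c, A_ds, d_ds, w_ds, A_mt, d_mt,
#'   w_mt}.
#' @export
twoPoolFitControl <- function() {
  list(
    start = c(c = 1,   A_ds = 0.9, d_ds = 0,  w_ds = 1.5, A_mt = 0.1, d_mt = -1, w_mt = 40),
    lower = c(c = 0.8, A_ds = 0,   d_ds = -1, w_ds = 0.3, A_mt = 0,   d_mt = -3, w_mt = 10),
    upper = c(c = 1.2, A_ds = 1,   d_ds = 1,  w_ds = 10,  A_mt = 1,   d_mt = 1,  w_mt = 100)
  )
}

# Core bounded Levenberg-Marquardt fit of one spectrum (already restricted
# to the fit region, NAs removed). Returns par, rss, converged.
fitSpectrumCore <- function(y, x, ctrl = twoPoolFitControl(), maxiter = 150L) {
  # convergence is reported through the info flag; nls.lm's own maxiter
  # warning would otherwise fire once per hard voxel
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = ctrl$start, lower = ctrl$lower, upper = ctrl$upper,
    fn = function(p, delta, obs) obs - twoPoolModel(p, delta),
    jac = twoPoolResidJac,
    delta = x, obs = y,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-13, ptol = 1e-13)))
  list(par = fit$par,
       rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

#' Fit the two-pool (DS + MT) Lorentzian model to one Z-spectrum
#'
#' Bounded nonlinear least squares of
#' \eqn{c - L_{ds} - L_{mt}} against the spectrum, restricted to the offsets
#' admitted by \code{fitRegion}. Offsets carrying \code{NA} are dropped;
#' fewer than 8 usable points invalidates the voxel.
#'
#' @param z numeric Z-spectrum aligned with \code{offsets(sched)}.
#' @param sched an [OffsetSchedule-class].
#' @param fitRegion predicate over offsets (see [defaultFitRegion()]).
#' @param control start values and bounds, see [twoPoolFitControl()].
#' @return list with \code{par} (named numeric(7)), \code{residualNorm},
#'   \code{converged}, \code{nPointsUsed}.
#' @export
#' @examples
#' sch <- buildOffsetSchedule()
#' truth <- c(c = 1, A_ds = 0.8, d_ds = 0, w_ds = 1.5, A_mt = 0.12, d_mt = -1, w_mt = 30)
#' z <- twoPoolModel(truth, offsets(sch))
#' fitTwoPool(z, sch)$par
fitTwoPool <- function(z, sched, fitRegion = defaultFitRegion(),
                       control = twoPoolFitControl()) {
  keep <- fitRegion(sched@offsets)
  x <- sched@offsets[keep]
  y <- z[keep]
  ok <- is.finite(y)
  nUsed <- sum(ok)
  if (nUsed < 8L) {
    return(list(par = stats::setNames(rep(NA_real_, 7L), TWO_POOL_PARAMS),
                residualNorm = NA_real_, converged = FALSE,
                nPointsUsed = nUsed))
  }
  f <- fitSpectrumCore(y[ok], x[ok], control)
  list(par = stats::setNames(f$par, TWO_POOL_PARAMS),
       residualNorm = f$rss, converged = f$converged, nPointsUsed = nUsed)
}

#' Voxelwise two-pool fitting of a Z-spectrum volume
#'
#' Applies [fitTwoPool()] to every valid voxel of a
#' [ZSpectrumVolume-class]. Voxels flagged invalid at normalization, or with
#' fewer than 8 usable offsets in the fit region, are skipped and marked
#' non-converged with \code{nPointsUsed} recording what was available.
#'
#' @param zvol a [ZSpectrumVolume-class].
#' @inheritParams fitTwoPool
#' @return a [TwoPoolFit-class].
#' @export
fitTwoPoolVolume <- function(zvol, fitRegion = defaultFitRegion(),
                             control = twoPoolFitControl()) {
  d <- gridDim(zvol)
  nv <- prod(d)
  keep <- fitRegion(zvol@schedule@offsets)
  x <- zvol@schedule@offsets[keep]
  zmat <- matrix(zvol@z, nrow = nv)[, keep, drop = FALSE]
  params <- matrix(NA_real_, nv, 7L)
  rss <- rep(NA_real_, nv)
  conv <- rep(FALSE, nv)
  nUsed <- integer(nv)
  idx <- which(as.vector(zvol@validMask))
  for (v in idx) {
    y <- zmat[v, ]
    ok <- is.finite(y)
    nUsed[v] <- sum(ok)
    if (nUsed[v] < 8L) next
    f <- fitSpectrumCore(y[ok], x[ok], control)
    params[v, ] <- f$par
    rss[v] <- f$rss
    conv[v] <- f$converged
  }
  new("TwoPoolFit",
      params       = array(params, c(d, 7L)),
      residualNorm = array(rss, d),
      converged    = array(conv, d),
      nPointsUsed  = array(nUsed, d),
      schedule     = zvol@schedule,
      fitRegion    = keep)
}

# Evaluate the fitted curve of every voxel at per-voxel offsets.
# `at` is either a scalar/vector recycled across voxels, or a matrix with one
# row per voxel. Returns a matrix (nvox x n offsets).
predictFitted <- function(fit, at) {
  d <- gridDim(fit)
  nv <- prod(d)
  P <- matrix(fit@params, nrow = nv)
  if (!is.matrix(at)) at <- matrix(at, nrow = nv, ncol = length(at), byrow = TRUE)
  out <- matrix(NA_real_, nv, ncol(at))
  for (j in seq_len(ncol(at))) {
    x <- at[, j]
    out[, j] <- P[, 1L] -
      lorentzianSafe(x, P[, 2L], P[, 3L], P[, 4L]) -
      lorentzianSafe(x, P[, 5L], P[, 6L], P[, 7L])
  }
  out
}

# Vectorized Lorentzian tolerating NA parameter rows (unfitted voxels).
lorentzianSafe <- function(delta, A, d0, w) {
  u <- (w / 2)^2
  A * u / (u + (delta - d0)^2)
}
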