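# Small phantom configurations shared across tests. All fixtures are built
# in code; nothing is read from disk.

# WM carrying only the two fitted pools (DS + MT). With the MT line at its
# realistic off-center position (-1 ppm) LD and MTRrex are zero at +3.5 ppm
# but MTRasym keeps the MT asymmetry; mtCenter = 0 gives a fully symmetric
# spectrum where all three metrics vanish.
twoPoolTissues <- function(mtCenter = -1) {
  list(
    WM = tissueTruth("WM", list(
      DS = poolTruth(0.80, 0, 1.4),
      MT = poolTruth(0.12, mtCenter, 30)), refIntensity = 700),
    background = tissueTruth("background", refIntensity = 0)
  )
}

# WM with an injected APT pool of known amplitude (and no NOE, so the
# ground-truth LD at +3.5 ppm is the injected amplitude itself).
aptOnlyTissues <- function(apt = 0.05, aptW = 1.0) {
  list(
    WM = tissueTruth("WM", list(
      DS  = poolTruth(0.76, 0, 1.4),
      MT  = poolTruth(0.12, -1, 30),
      APT = poolTruth(apt, 3.5, aptW)), refIntensity = 700),
    background = tissueTruth("background", refIntensity = 0)
  )
}

# WM with an NOE pool beside a symmetric DS line (no MT, whose own
# asymmetry would otherwise mix in): MTRasym is exactly -amplitude at
# +/-3.5 ppm while LD / MTRrex at +3.5 ppm stay near zero.
noeOnlyTissues <- function(noe = 0.05, noeW = 1.0) {
  list(
    WM = tissueTruth("WM", list(
      DS  = poolTruth(0.80, 0, 1.4),
      NOE = poolTruth(noe, -3.5, noeW)), refIntensity = 700),
    background = tissueTruth("background", refIntensity = 0)
  )
}

# One-scan, deterministic phantom configuration.
singleScanConfig <- function(tissues, grid = c(16L, 16L, 1L), noiseSd = 0,
                             b0 = b0FieldSpec("constant", 0), seed = 1L,
                             tumor = FALSE) {
  phantomConfig(gridShape = grid, tissues = tissues,
                participants = 1L, scanners = 1L, sessions = 1L,
                repeats = 1L, noiseSd = noiseSd, b0Field = b0,
                variance = varianceComponents(0, 0, 0, 0),
                tumor = tumor, seed = seed)
}

# Physiologically representative interior parameter draws for the fit
# oracle (keeping A_mt well away from 0, where the MT center and width are
# unidentifiable).
randomTwoPoolPars <- function(n) {
  t(replicate(n, c(
    c    = runif(1, 0.9, 1.1),
    A_ds = runif(1, 0.6, 0.95),
    d_ds = runif(1, -0.3, 0.3),
    w_ds = runif(1, 1, 3),
    A_mt = runif(1, 0.05, 0.3),
    d_mt = runif(1, -2.5, 0),
    w_mt = runif(1, 20, 80))))
}

# Build a one-voxel ZSpectrumVolume directly from a spectrum vector.
oneVoxelZ <- function(z, sched) {
  new("ZSpectrumVolume", z = array(z, c(1L, 1L, 1L, length(z))),
      schedule = sched, validMask = array(TRUE, c(1L, 1L, 1L)),
      b0Corrected = FALSE)
}

# Build a one-voxel TwoPoolFit with given parameters (marked converged).
oneVoxelFit <- function(par, sched, fitRegion = defaultFitRegion()) {
  new("TwoPoolFit",
      params = array(unname(par), c(1L, 1L, 1L, 7L)),
      residualNorm = array(0, c(1L, 1L, 1L)),
      converged = array(TRUE, c(1L, 1L, 1L)),
      nPointsUsed = array(sum(fitRegion(sched@offsets)), c(1L, 1L, 1L)),
      schedule = sched, fitRegion = fitRegion(sched@offsets))
}

zeroB0 <- function(grid = c(1L, 1L, 1L)) {
  new("B0Map", shift = array(0, grid), valid = array(TRUE, grid))
}
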