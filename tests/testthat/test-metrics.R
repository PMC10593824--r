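test_that("metric arithmetic matches the closed forms on a hand-built voxel", {
  sch <- buildOffsetSchedule()
  par <- c(c = 1, A_ds = 0.5, d_ds = 0, w_ds = 1.5,
           A_mt = 0.12, d_mt = -1, w_mt = 40)
  zfit <- twoPoolModel(unname(par), offsets(sch))
  fit <- oneVoxelFit(par, sch)
  b0 <- zeroB0()

  # spectrum identical to the fit: LD = 0, MTRrex = 0
  m0 <- computeMetricMaps(oneVoxelZ(zfit, sch), fit, b0)
  expect_equal(m0@ldApt[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(m0@mtrRexApt[1, 1, 1], 0, tolerance = 1e-12)

  # force z(+3.5) = 0.65 while the fitted curve gives 0.70 there
  par2 <- par; par2[["c"]] <- 0.70 + sum(
    lorentzian(3.5, 0.5, 0, 1.5), lorentzian(3.5, 0.12, -1, 40))
  fit2 <- oneVoxelFit(par2, sch)
  z2 <- twoPoolModel(unname(par2), offsets(sch))
  z2[offsetIndex(sch, 3.5)] <- 0.65
  m2 <- computeMetricMaps(oneVoxelZ(z2, sch), fit2, b0)
  expect_equal(m2@mtrRexApt[1, 1, 1], (1 / 0.65 - 1 / 0.70) * 100,
               tolerance = 1e-9)  # 10.989...
  expect_equal(m2@ldApt[1, 1, 1], 5, tolerance = 1e-9)
})

test_that("MTRasym vanishes on symmetric spectra and subtracts directly", {
  sch <- buildOffsetSchedule()
  par <- c(1, 0.8, 0, 1.5, 0, -1, 40)   # symmetric: DS only, centered
  z <- twoPoolModel(par, offsets(sch))
  m <- computeMetricMaps(oneVoxelZ(z, sch), oneVoxelFit(par, sch), zeroB0())
  expect_equal(m@mtrAsymApt[1, 1, 1], 0, tolerance = 1e-12)

  z[offsetIndex(sch, -3.5)] <- 0.70
  z[offsetIndex(sch, 3.5)] <- 0.65
  m2 <- computeMetricMaps(oneVoxelZ(z, sch), oneVoxelFit(par, sch), zeroB0())
  expect_equal(m2@mtrAsymApt[1, 1, 1], 5, tolerance = 1e-9)
})

test_that("the MTRrex * z * zfit = LD identity holds voxelwise", {
  cfg <- singleScanConfig(aptOnlyTissues(), grid = c(10L, 10L, 1L),
                          noiseSd = 0.005, b0 = b0FieldSpec("gradient", 0.15),
                          seed = 8L)
  ds <- generateDataset(cfg)
  q <- runQuantify(ds)
  r <- q$results[[1]]
  v <- validMask(r$maps)
  expect_true(any(v))
  # reconstruct the fractional ingredients exactly as the pipeline sees them
  nv <- prod(gridDim(r$maps))
  zPos <- matrix(r$zCorrected@z, nv)[, offsetIndex(r$zCorrected@schedule, 3.5)]
  shift <- as.vector(shifts(r$b0)); shift[!as.vector(validMask(r$b0))] <- 0
  zfitPos <- predictFitted(r$fit, matrix(3.5 + shift, ncol = 1))[, 1]
  ld <- r$maps@ldApt / 100; rex <- r$maps@mtrRexApt / 100
  lhs <- (as.vector(rex) * zPos * zfitPos)[as.vector(v)]
  rhs <- as.vector(ld)[as.vector(v)]
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("pools on one side of water separate in the metrics", {
  # APT only: LD, MTRrex, MTRasym all positive ~5%
  dsA <- generateDataset(singleScanConfig(aptOnlyTissues(), grid = c(10L, 10L, 1L)))
  rA <- runQuantify(dsA)$results[[1]]
  wmA <- dsA@masks$WM
  expect_gt(roiMean(metricMap(rA$maps, "LD"), wmA, validMask(rA$maps))$value, 4)
  expect_gt(roiMean(metricMap(rA$maps, "MTRrex"), wmA, validMask(rA$maps))$value, 4)
  expect_gt(roiMean(metricMap(rA$maps, "MTRasym"), wmA, validMask(rA$maps))$value, 4)

  # NOE only: MTRasym ~ -5% while LD/MTRrex at +3.5 stay near 0
  dsN <- generateDataset(singleScanConfig(noeOnlyTissues(), grid = c(10L, 10L, 1L)))
  rN <- runQuantify(dsN)$results[[1]]
  wmN <- dsN@masks$WM
  asym <- roiMean(metricMap(rN$maps, "MTRasym"), wmN, validMask(rN$maps))$value
  expect_lt(abs(asym + 5), 0.1)
  expect_lt(abs(roiMean(metricMap(rN$maps, "LD"), wmN, validMask(rN$maps))$value), 0.3)
  expect_lt(abs(roiMean(metricMap(rN$maps, "MTRrex"), wmN, validMask(rN$maps))$value), 0.5)
})

test_that("the z floor invalidates voxels that would blow up the inversion", {
  sch <- buildOffsetSchedule()
  par <- c(1, 0.8, 0, 1.5, 0.12, -1, 40)
  z <- twoPoolModel(par, offsets(sch))
  z[offsetIndex(sch, 3.5)] <- 0.01   # below the 0.05 floor
  m <- computeMetricMaps(oneVoxelZ(z, sch), oneVoxelFit(par, sch), zeroB0())
  expect_false(validMask(m)[1, 1, 1])
  expect_true(is.na(m@mtrRexApt[1, 1, 1]))
  expect_true(is.na(m@ldApt[1, 1, 1]))
})

test_that("metric validity is inherited from fit, reference and B0", {
  sch <- buildOffsetSchedule()
  par <- c(1, 0.8, 0, 1.5, 0.12, -1, 40)
  z <- twoPoolModel(par, offsets(sch))
  fit <- oneVoxelFit(par, sch)
  fit@converged[1, 1, 1] <- FALSE
  m <- computeMetricMaps(oneVoxelZ(z, sch), fit, zeroB0())
  expect_false(validMask(m)[1, 1, 1])
})
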