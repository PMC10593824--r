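test_that("the Lorentzian line has its textbook geometry", {
  expect_identical(lorentzian(0.7, 0.8, 0.7, 2), 0.8)        # peak at center
  expect_identical(lorentzian(0.7 + 1, 0.8, 0.7, 2), 0.4)    # half max at fwhm/2
  expect_identical(lorentzian(0.7 - 1, 0.8, 0.7, 2), 0.4)    # symmetric
  expect_equal(lorentzian(3, 0.8, 0, 2), 0.8 / 10)           # 0.8 * 1/(1+9)
  expect_error(lorentzian(0, 0.5, 0, 0), "fwhm")
  expect_error(lorentzian(0, 0.5, 0, -1), "fwhm")
})

test_that("noiseless two-pool spectra are recovered to high precision", {
  sch <- buildOffsetSchedule()
  set.seed(42)
  pars <- randomTwoPoolPars(25)
  for (i in seq_len(nrow(pars))) {
    truth <- pars[i, ]
    z <- twoPoolModel(truth, offsets(sch))
    f <- fitTwoPool(z, sch)
    expect_true(f$converged)
    expect_lt(max(abs((f$par - truth) / truth)), 1e-4)
  }
})

test_that("an APT peak outside the fit region barely perturbs the fit", {
  sch <- buildOffsetSchedule()
  truth <- c(c = 1, A_ds = 0.8, d_ds = 0.05, w_ds = 1.6,
             A_mt = 0.12, d_mt = -1, w_mt = 35)
  z <- twoPoolModel(truth, offsets(sch)) -
    lorentzian(offsets(sch), 0.05, 3.5, 1)
  f <- fitTwoPool(z, sch)
  expect_true(f$converged)
  # the APT tails that leak into the fit region (~2e-3 of z near +/-1 ppm)
  # bound how well the individual parameters can be recovered
  expect_lt(max(abs((f$par - truth) / truth)), 0.05)
  # what matters downstream: the fitted baseline at +3.5 ppm
  expect_equal(twoPoolModel(unname(f$par), 3.5),
               unname(twoPoolModel(truth, 3.5)), tolerance = 2e-3)
})

test_that("a flat spectrum collapses to zero-amplitude pools", {
  sch <- buildOffsetSchedule()
  f <- fitTwoPool(rep(1, 43), sch)
  expect_lt(f$par[["A_ds"]], 1e-6)
  expect_lt(f$par[["A_mt"]], 1e-6)
  expect_equal(f$par[["c"]], 1, tolerance = 1e-6)
})

test_that("fitting is invariant to the input ordering of offsets", {
  set.seed(7)
  scrambled <- sample(offsets(buildOffsetSchedule()))
  schS <- buildOffsetSchedule(offsets = scrambled)
  sch <- buildOffsetSchedule()
  expect_identical(offsets(schS), offsets(sch))
  truth <- c(1, 0.75, -0.1, 1.8, 0.15, -1.5, 45)
  z <- twoPoolModel(truth, offsets(sch))
  expect_identical(fitTwoPool(z, schS)$par, fitTwoPool(z, sch)$par)
})

test_that("sparse or NA-ridden spectra are handled voxelwise", {
  sch <- buildOffsetSchedule()
  truth <- c(1, 0.8, 0, 1.5, 0.1, -1, 40)
  z <- twoPoolModel(truth, offsets(sch))
  # drop some fit-region points to NA: they are excluded, not fatal
  zNA <- z
  zNA[offsetIndex(sch, c(0, 0.25, 9))] <- NA
  f <- fitTwoPool(zNA, sch)
  expect_identical(f$nPointsUsed, sum(defaultFitRegion()(offsets(sch))) - 3L)
  expect_true(f$converged)
  # fewer than 8 usable points invalidates the voxel
  zFew <- rep(NA_real_, 43)
  zFew[offsetIndex(sch, c(-100, -50, 0, 50, 100))] <- 1
  fFew <- fitTwoPool(zFew, sch)
  expect_false(fFew$converged)
  expect_true(all(is.na(fFew$par)))
})

test_that("volume fitting skips invalid voxels and records counts", {
  sch <- buildOffsetSchedule()
  truth <- c(1, 0.8, 0, 1.5, 0.1, -1, 40)
  z <- array(NA_real_, c(2L, 1L, 1L, 43L))
  z[1, 1, 1, ] <- twoPoolModel(truth, offsets(sch))
  vm <- array(c(TRUE, FALSE), c(2L, 1L, 1L))
  zvol <- new("ZSpectrumVolume", z = z, schedule = sch, validMask = vm,
              b0Corrected = FALSE)
  fit <- fitTwoPoolVolume(zvol)
  expect_true(fit@converged[1, 1, 1])
  expect_false(fit@converged[2, 1, 1])
  expect_identical(fit@nPointsUsed[2, 1, 1], 0L)
  expect_equal(fit@params[1, 1, 1, ], unname(truth), tolerance = 1e-5)
})
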