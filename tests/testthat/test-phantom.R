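test_that("identical configuration and seed reproduce the dataset bit for bit", {
  cfg <- phantomConfig(gridShape = c(8L, 8L, 1L), participants = 2L,
                       scanners = 2L, sessions = 2L, repeats = 2L,
                       noiseSd = 0.005,
                       b0Field = b0FieldSpec("smooth", 0.15), seed = 11L)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(lapply(d1@scans, slot, "data"),
                   lapply(d2@scans, slot, "data"))
  expect_identical(d1@truth, d2@truth)
  expect_identical(d1@b0Field, d2@b0Field)
})

test_that("without stochastic terms every scan of a participant is identical", {
  cfg <- phantomConfig(gridShape = c(8L, 8L, 1L), participants = 1L,
                       scanners = 2L, sessions = 2L, repeats = 2L,
                       noiseSd = 0, b0Field = b0FieldSpec("constant", 0),
                       variance = varianceComponents(0, 0, 0, 0), seed = 2L)
  ds <- generateDataset(cfg)
  ref <- ds@scans[[1]]@data
  for (s in ds@scans) expect_identical(s@data, ref)
})

test_that("noiseless spectra are bounded and dip at the water line", {
  cfg <- singleScanConfig(twoPoolTissues(), grid = c(8L, 8L, 1L))
  ds <- generateDataset(cfg)
  z <- normalizeZSpectra(ds@scans[[1]])
  wm <- which(ds@masks$WM, arr.ind = TRUE)[1, ]
  spec <- z@z[wm[1], wm[2], wm[3], ]
  tis <- cfg$tissues$WM
  ampSum <- sum(vapply(tis$pools, `[[`, 1, "amplitude"))
  expect_true(all(spec <= tis$baseline + 1e-12))
  expect_true(all(spec >= tis$baseline - ampSum - 1e-12))
  # with b0 = 0 the sampled minimum sits at the DS center (0 ppm)
  expect_identical(offsets(z)[which.min(spec)], 0)
})

test_that("truth summary reports the exact realized amplitudes", {
  cfg <- singleScanConfig(aptOnlyTissues(), grid = c(6L, 6L, 1L))
  tr <- truthSummary(generateDataset(cfg))
  # one scan: (#tissues with pools) x (#pools) rows
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$realized, tr$nominal)

  # multiplicative session perturbations: sample CV over many sessions
  # approaches the configured CV
  nSess <- 400L
  cfg2 <- phantomConfig(gridShape = c(2L, 2L, 1L), tissues = aptOnlyTissues(),
                        participants = 1L, scanners = 1L, sessions = nSess,
                        repeats = 1L, noiseSd = 0,
                        b0Field = b0FieldSpec("constant", 0),
                        variance = varianceComponents(0, 0.05, 0, 0),
                        tumor = FALSE, seed = 5L)
  tr2 <- truthSummary(generateDataset(cfg2))
  apt <- tr2$realized[tr2$pool == "APT"]
  expect_length(apt, nSess)
  cv <- sd(apt) / mean(apt)
  expect_lt(abs(cv - 0.05), 3 * 0.05 / sqrt(nSess))
})

test_that("inconsistent designs are rejected or warned about", {
  expect_warning(
    phantomConfig(gridShape = c(4L, 4L, 1L), participants = 1L,
                  scanners = 1L, sessions = 1L, repeats = 1L,
                  variance = varianceComponents(0, 0, 0.05, 0), seed = 1L),
    "not estimable")
  cfg <- singleScanConfig(twoPoolTissues(), grid = c(6L, 6L, 1L),
                          b0 = b0FieldSpec("constant", 1.5))
  expect_error(generateDataset(cfg), "1 ppm")
  expect_error(phantomConfig(participants = 3L, plan = "minimal",
                             scanners = 1L),
               "minimal plan")
})

test_that("tissue invariants are enforced at construction", {
  expect_error(tissueTruth("WM", list(MT = poolTruth(0.1, -1, 30))), "DS pool")
  expect_error(tissueTruth("WM", list(DS = poolTruth(0.9, 0, 2),
                                      MT = poolTruth(0.2, -1, 30))),
               "baseline")
  expect_error(poolTruth(1.2, 0, 1))
  expect_error(poolTruth(0.5, 0, -1))
})

test_that("the minimal plan generates exactly the level-defining scans", {
  cfg <- phantomConfig(gridShape = c(4L, 4L, 1L), participants = 2L,
                       scanners = 2L, sessions = 2L, repeats = 2L,
                       plan = "minimal", noiseSd = 0,
                       b0Field = b0FieldSpec("constant", 0),
                       variance = varianceComponents(0, 0, 0, 0), seed = 1L)
  m <- generateDataset(cfg)@manifest
  expect_identical(nrow(m), 8L)  # 4 scans per participant
  p1 <- m[m$participant == "P01", ]
  expect_setequal(p1$scan, c("P01_A_s1_r1", "P01_A_s1_r2",
                             "P01_A_s2_r1", "P01_B_s1_r1"))
})
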