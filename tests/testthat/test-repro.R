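# Build a minimal reproducibility table by hand: participants x the crossed
# 2x2x2 scan plan, one ROI, one metric.
makeTable <- function(values, participants = names(values), roi = "WM",
                      metric = "LD") {
  rows <- list()
  for (p in participants) {
    v <- values[[p]]
    stopifnot(nrow(v) >= 1)
    for (i in seq_len(nrow(v)))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, scanner = v$scanner[i], session = v$session[i],
        repeat. = v$repeat.[i], roi = roi, metric = metric,
        value = v$value[i], nVoxels = 100L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

scanRow <- function(scanner, session, repeat., value)
  data.frame(scanner = scanner, session = session, repeat. = repeat.,
             value = value, stringsAsFactors = FALSE)

test_that("ROI averaging reports value, count and empty-ROI status", {
  m <- array(5, c(4L, 4L, 1L))
  mask <- array(FALSE, c(4L, 4L, 1L)); mask[1:2, 1:2, 1] <- TRUE
  r <- roiMean(m, mask)
  expect_identical(r, list(value = 5, nVoxels = 4L, status = "ok"))
  valid <- array(FALSE, c(4L, 4L, 1L))
  e <- roiMean(m, mask, valid)
  expect_identical(e$status, "empty ROI")
  expect_true(is.na(e$value))
  expect_error(roiMean(m, array(TRUE, c(2L, 2L, 1L))), "does not match")
})

test_that("covWithin implements the n-1 within-subject COV", {
  expect_identical(covWithin(c(10, 10)), 0)
  expect_equal(covWithin(c(9, 11)), 100 * sqrt(2) / 10)  # 14.142...
  # invariances: positive rescaling and permutation
  x <- c(4.2, 5.1, 4.9, 5.6)
  expect_equal(covWithin(3.7 * x), covWithin(x))
  expect_equal(covWithin(rev(x)), covWithin(x))
  # negative values: |mean| in the denominator
  expect_equal(covWithin(-x), covWithin(x))
  expect_identical(attr(covWithin(c(1, NA)), "reason"),
                   "fewer than 2 finite values")
  expect_identical(attr(covWithin(c(-1, 1)), "reason"), "zero mean")
})

test_that("per-participant COV approaches the injected CV as repeats grow", {
  set.seed(31)
  cv <- 0.05
  for (nRep in c(50L, 500L)) {
    x <- 5 * rlnorm(nRep, 0, cv)
    expect_lt(abs(covWithin(x) / 100 - cv), 3 * cv / sqrt(nRep))
  }
})

test_that("covByLevel selects the level's scans and summarizes the group", {
  # three participants whose within-session pairs give COVs 0.20, 0.56, 1.01
  mkPair <- function(cov) {
    d <- cov * sqrt(2) * 10 / 100
    list(scanRow("A", 1L, 1L, 10 - d / 2), scanRow("A", 1L, 2L, 10 + d / 2))
  }
  vals <- lapply(c(P1 = 0.20, P2 = 0.56, P3 = 1.01),
                 function(cv) do.call(rbind, mkPair(cv)))
  tab <- makeTable(vals)
  cs <- covByLevel(tab, "within_session", "WM", "LD")
  expect_equal(unname(cs$perParticipant), c(0.20, 0.56, 1.01), tolerance = 1e-9)
  expect_equal(cs$median, 0.56, tolerance = 1e-9)
  expect_identical(cs$n, 3L)

  # identical repeats: median 0 and IQR [0, 0]
  same <- lapply(c(P1 = 0, P2 = 0, P3 = 0, P4 = 0), function(.)
    rbind(scanRow("A", 1L, 1L, 7), scanRow("A", 1L, 2L, 7)))
  cs0 <- covByLevel(makeTable(same), "within_session", "WM", "LD")
  expect_identical(c(cs0$median, cs0$q1, cs0$q3), c(0, 0, 0))

  # a participant missing the second repeat is excluded with a reason
  vals$P3 <- vals$P3[1, , drop = FALSE]
  cs1 <- covByLevel(makeTable(vals), "within_session", "WM", "LD")
  expect_identical(cs1$n, 2L)
  expect_match(cs1$excluded$P3, "1 of 2")
})

test_that("level selections pick the scans the design prescribes", {
  v <- rbind(scanRow("A", 1L, 1L, 10), scanRow("A", 1L, 2L, 11),
             scanRow("A", 2L, 1L, 12), scanRow("A", 2L, 2L, 13),
             scanRow("B", 1L, 1L, 14), scanRow("B", 1L, 2L, 15),
             scanRow("B", 2L, 1L, 16), scanRow("B", 2L, 2L, 17))
  tab <- makeTable(list(P1 = v))
  sel <- defaultLevelSelection()
  expect_identical(tab$value[sel$within_session(tab)], c(10, 11))
  expect_identical(tab$value[sel$between_session(tab)], c(10, 12))
  expect_identical(tab$value[sel$between_scanner(tab)], c(10, 14))
  expect_identical(sum(sel$all_sessions(tab)), 8L)
})

test_that("Bland-Altman statistics and symmetries", {
  b0 <- blandAltman(c(3, 4, 5), c(3, 4, 5))
  expect_identical(c(b0$bias, b0$loaLow, b0$loaHigh), c(0, 0, 0))

  m1 <- c(10, 9, 11, 10); m2 <- c(9, 10, 10, 11)   # d = 1,-1,1,-1
  b <- blandAltman(m1, m2)
  expect_equal(b$sdDiff, sqrt(4 / 3), tolerance = 1e-9)  # 1.1547
  expect_equal(b$loaHigh, 1.96 * sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(b$loaLow, -b$loaHigh, tolerance = 1e-9)

  swapped <- blandAltman(m2, m1)
  expect_equal(swapped$bias, -b$bias)
  expect_equal(swapped$loaHigh - swapped$loaLow, b$loaHigh - b$loaLow)
  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("about 95% of normal differences fall inside the limits of agreement", {
  set.seed(99)
  n <- 4000L
  m1 <- rnorm(n, 10, 1); m2 <- rnorm(n, 10, 1)
  b <- blandAltman(m1, m2)
  frac <- mean(b$pairs$difference >= b$loaLow & b$pairs$difference <= b$loaHigh)
  expect_lt(abs(frac - 0.95), 0.02)
})

test_that("the mixed-effects test reports a null effect for identical data", {
  same <- lapply(stats::setNames(nm = paste0("P", 1:6)), function(.)
    rbind(scanRow("A", 1L, 1L, 5), scanRow("A", 1L, 2L, 5)))
  r <- mixedEffectTest(makeTable(same), "WM", "LD", "within_session")
  expect_identical(r$estimate, 0)
  expect_false(r$significant)
})

test_that("the mixed-effects test flags an injected session shift", {
  set.seed(17)
  nP <- 12L
  vals <- lapply(stats::setNames(nm = sprintf("P%02d", 1:nP)), function(.) {
    base <- rnorm(1, 5, 1)
    rbind(scanRow("A", 1L, 1L, base + rnorm(1, 0, 0.2)),
          scanRow("A", 2L, 1L, base + 2 + rnorm(1, 0, 0.2)))
  })
  r <- mixedEffectTest(makeTable(vals), "WM", "LD", "between_session")
  expect_lt(r$pValue, 0.001)
  expect_equal(r$estimate, 2, tolerance = 0.5)
  expect_identical(r$nParticipants, nP)
})

test_that("building the repro table logs empty ROIs instead of failing", {
  cfg <- singleScanConfig(aptOnlyTissues(), grid = c(8L, 8L, 1L),
                          noiseSd = 0.002, seed = 21L)
  ds <- generateDataset(cfg)
  q <- runQuantify(ds)
  masks <- ds@masks
  masks$ghost <- array(FALSE, gridDim(q$results[[1]]$maps))  # empty ROI
  tab <- buildReproTable(q, masks)
  expect_false("ghost" %in% tab$roi)
  exc <- attr(tab, "excluded")
  expect_true("ghost" %in% exc$roi)
  expect_identical(unique(exc$reason[exc$roi == "ghost"]), "empty ROI")
  expect_true(all(is.finite(tab$value)))
})
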