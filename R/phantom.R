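#' Define a saturation pool for the synthetic phantom
#'
#' @param amplitude peak saturation fraction, in [0, 1].
#' @param center pool center (ppm), in [-100, 100].
#' @param fwhm full width at half maximum (ppm), > 0.
#' @return classed list of pool parameters.
#' @export
poolTruth <- function(amplitude, center, fwhm) {
  stopifnot(amplitude >= 0, amplitude <= 1, fwhm > 0,
            center >= -100, center <= 100)
  structure(list(amplitude = amplitude, center = center, fwhm = fwhm),
            class = "poolTruth")
}

#' Define a tissue for the synthetic phantom
#'
#' A tissue is a named set of saturation pools (a DS pool is mandatory for
#' non-background tissues), a baseline (the unsaturated normalized level,
#' usually 1) and a reference-image intensity used to scale the synthetic
#' raw signal. The pool amplitudes must sum to less than the baseline so the
#' noiseless spectrum stays non-negative everywhere.
#'
#' @param label tissue label, one of \code{WM, GM, CSF, CE_tumor,
#'   necrotic_core, background}.
#' @param pools named list of [poolTruth()] entries (names such as
#'   \code{DS, MT, APT, NOE}).
#' @param baseline unsaturated normalized signal, in (0, 1].
#' @param refIntensity reference-image intensity (arbitrary units).
#' @return classed list describing the tissue.
#' @export
tissueTruth <- function(label, pools = list(), baseline = 1, refIntensity = 1000) {
  label <- match.arg(label, c("WM", "GM", "CSF", "CE_tumor", "necrotic_core",
                              "background"))
  stopifnot(baseline > 0, baseline <= 1, refIntensity >= 0)
  if (label != "background") {
    if (!"DS" %in% names(pools))
      stop(sprintf("tissue '%s' must contain a DS pool", label))
    amps <- vapply(pools, `[[`, 1, "amplitude")
    if (sum(amps) >= baseline)
      stop(sprintf("tissue '%s': pool amplitudes sum to %.3f >= baseline %.3f",
                   label, sum(amps), baseline))
  }
  structure(list(label = label, pools = pools, baseline = baseline,
                 refIntensity = refIntensity),
            class = "tissueTruth")
}

#' Default synthetic tissue set
#'
#' Four-pool (DS, MT, APT, NOE) tissue parameterizations chosen so that the
#' emergent metric scales are in the range reported for 3T brain
#' APT-weighted imaging: WM MTRasym around -1%, contrast-enhancing tumor LD
#' around 6.5% with MTRrex near 20%. These are synthetic stand-ins, not
#' measured tissue parameters.
#'
#' @return named list of [tissueTruth()] entries.
#' @export
defaultTissues <- function() {
  list(
    WM = tissueTruth("WM", list(
      DS  = poolTruth(0.76, 0,    1.4),
      MT  = poolTruth(0.12, -1.0, 30),
      APT = poolTruth(0.05, 3.5,  1.2),
      NOE = poolTruth(0.053, -3.5, 2.5)), refIntensity = 700),
    GM = tissueTruth("GM", list(
      DS  = poolTruth(0.80, 0,    1.6),
      MT  = poolTruth(0.09, -1.0, 30),
      APT = poolTruth(0.045, 3.5, 1.2),
      NOE = poolTruth(0.045, -3.5, 2.5)), refIntensity = 850),
    CSF = tissueTruth("CSF", list(
      DS  = poolTruth(0.93, 0,    1.0),
      MT  = poolTruth(0.015, -1.0, 30),
      APT = poolTruth(0.01, 3.5,  1.2),
      NOE = poolTruth(0.005, -3.5, 2.5)), refIntensity = 1000),
    CE_tumor = tissueTruth("CE_tumor", list(
      DS  = poolTruth(0.60, 0,    4.0),
      MT  = poolTruth(0.28, -1.0, 50),
      APT = poolTruth(0.062, 3.5, 1.3),
      NOE = poolTruth(0.035, -3.5, 2.5)), refIntensity = 900),
    necrotic_core = tissueTruth("necrotic_core", list(
      DS  = poolTruth(0.60, 0,    4.2),
      MT  = poolTruth(0.26, -1.0, 45),
      APT = poolTruth(0.058, 3.5, 1.3),
      NOE = poolTruth(0.030, -3.5, 2.5)), refIntensity = 950),
    background = tissueTruth("background", refIntensity = 0)
  )
}

#' Multiplicative variance components of the reproducibility design
#'
#' Each component is a coefficient of variation (fraction) applied as an
#' independent multiplicative lognormal perturbation (ln-sd = CV, which
#' keeps amplitudes positive) to every pool amplitude at its design level:
#' per participant, per participant-scanner, per participant-scanner-session
#' and per individual scan (within session).
#'
#' @param withinSession scan-to-scan CV within one session.
#' @param betweenSession session-to-session CV on one scanner.
#' @param betweenScanner scanner-to-scanner CV.
#' @param betweenParticipant participant-to-participant CV.
#' @return classed list of the four CVs.
#' @export
varianceComponents <- function(withinSession = 0.005, betweenSession = 0.01,
                               betweenScanner = 0.02, betweenParticipant = 0.10) {
  v <- list(withinSession = withinSession, betweenSession = betweenSession,
            betweenScanner = betweenScanner, betweenParticipant = betweenParticipant)
  stopifnot(all(unlist(v) >= 0))
  structure(v, class = "varianceComponents")
}

#' Deterministic concentric tissue layout
#'
#' Assigns tissue labels on a 3D grid as nested rectangular blocks (in the
#' max-norm distance from the grid center): a background frame, a WM shell,
#' a GM band and a CSF core, with an optional tumor insert (CE rim around a
#' necrotic core) placed inside the WM shell. Identical across slices;
#' mask-exact and reproducible by construction.
#'
#' @param gridShape integer(3) grid dimensions.
#' @param tumor logical, place the tumor insert (skipped when the grid is
#'   too small to hold it).
#' @return character 3D array of tissue labels.
#' @export
concentricLayout <- function(gridShape, tumor = TRUE) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  dx <- abs(seq_len(nx) - cx) / (nx / 2)
  dy <- abs(seq_len(ny) - cy) / (ny / 2)
  dmax <- outer(dx, dy, pmax)
  lab <- matrix("background", nx, ny)
  lab[dmax <= 0.92] <- "WM"
  lab[dmax <= 0.45] <- "GM"
  lab[dmax <= 0.25] <- "CSF"
  if (tumor) {
    tx <- seq.int(max(1L, round(0.78 * nx)), min(nx, round(0.95 * nx)))
    ty <- seq.int(max(1L, round(0.40 * ny)), min(ny, round(0.62 * ny)))
    tx <- tx[lab[tx, max(1L, ty[1])] != "background"]
    if (length(tx) >= 2L && length(ty) >= 2L) {
      lab[tx, ty] <- "CE_tumor"
      if (length(tx) >= 4L && length(ty) >= 4L) {
        nxc <- tx[-c(1L, length(tx))][-1L]; nyc <- ty[-c(1L, length(ty))][-1L]
        nxc <- tx[seq.int(2L, length(tx) - 1L)]
        nyc <- ty[seq.int(2L, length(ty) - 1L)]
        lab[nxc, nyc] <- "necrotic_core"
      }
    }
  }
  array(rep(lab, nz), dim = c(nx, ny, nz))
}

#' Specify the simulated B0 inhomogeneity field
#'
#' @param type \code{"constant"} (uniform shift), \code{"gradient"} (linear
#'   ramp along x from -amplitude to +amplitude) or \code{"smooth"} (smooth
#'   random low-order cosine field with the given peak amplitude, drawn from
#'   the dataset seed).
#' @param amplitude shift scale in ppm; fields exceeding 1 ppm anywhere are
#'   rejected at generation.
#' @return classed list describing the field.
#' @export
b0FieldSpec <- function(type = c("gradient", "constant", "smooth"),
                        amplitude = 0.2) {
  type <- match.arg(type)
  structure(list(type = type, amplitude = amplitude), class = "b0FieldSpec")
}

buildB0Field <- function(spec, gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  field <- switch(spec$type,
    constant = array(spec$amplitude, gridShape),
    gradient = {
      ramp <- if (nx == 1L) 0 else spec$amplitude * (2 * (seq_len(nx) - 1) / (nx - 1) - 1)
      array(rep(ramp, ny * nz), gridShape)
    },
    smooth = {
      # seeded by the caller's RNG state
      a <- stats::rnorm(6)
      gx <- (seq_len(nx) - 1) / max(1, nx - 1)
      gy <- (seq_len(ny) - 1) / max(1, ny - 1)
      f2 <- a[1] * outer(cos(pi * gx), rep(1, ny)) +
            a[2] * outer(rep(1, nx), cos(pi * gy)) +
            a[3] * outer(cos(2 * pi * gx), cos(pi * gy)) +
            a[4] * outer(sin(pi * gx), sin(pi * gy)) +
            a[5] * outer(cos(pi * gx), cos(2 * pi * gy)) +
            a[6]
      f2 <- f2 / max(abs(f2)) * spec$amplitude
      array(rep(f2, nz), gridShape)
    })
  if (any(abs(field) > 1))
    stop("simulated B0 field exceeds 1 ppm; reduce the amplitude")
  field
}

#' Configure a synthetic reproducibility phantom
#'
#' Collects everything [generateDataset()] needs: grid, tissues, offset
#' schedule, acquisition noise, B0 field, the reproducibility design
#' (participants x scanners x sessions x repeats) and the seed. The design
#' \code{plan} is either \code{"crossed"} (every scanner/session/repeat
#' combination for every participant) or \code{"minimal"} (only the scans
#' the three reproducibility levels require: both repeats of session 1 on
#' scanner A, repeat 1 of session 2 on scanner A, repeat 1 of session 1 on
#' scanner B).
#'
#' @param gridShape integer(3) grid dimensions.
#' @param tissues named list of [tissueTruth()] entries.
#' @param sched an [OffsetSchedule-class].
#' @param noiseSd Gaussian noise sd as a fraction of the reference intensity.
#' @param b0Field a [b0FieldSpec()].
#' @param participants,scanners,sessions,repeats design counts (>= 1).
#' @param plan \code{"crossed"} or \code{"minimal"}.
#' @param variance a [varianceComponents()].
#' @param tumor logical, include the tumor insert in the layout.
#' @param seed integer RNG seed.
#' @return validated configuration list (class \code{"phantomConfig"}).
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 4L),
                          tissues = defaultTissues(),
                          sched = buildOffsetSchedule(),
                          noiseSd = 0.005,
                          b0Field = b0FieldSpec("gradient", 0.2),
                          participants = 6L, scanners = 2L,
                          sessions = 2L, repeats = 2L,
                          plan = c("crossed", "minimal"),
                          variance = varianceComponents(),
                          tumor = TRUE,
                          seed = 1L) {
  plan <- match.arg(plan)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L),
            noiseSd >= 0, participants >= 1L, scanners >= 1L,
            sessions >= 1L, repeats >= 1L)
  if (plan == "minimal" && (scanners < 2L || sessions < 2L || repeats < 2L))
    stop("the minimal plan needs >= 2 scanners, sessions and repeats")
  cfg <- list(gridShape = as.integer(gridShape), tissues = tissues,
              schedule = sched, noiseSd = noiseSd, b0Field = b0Field,
              design = list(participants = as.integer(participants),
                            scanners = as.integer(scanners),
                            sessions = as.integer(sessions),
                            repeats = as.integer(repeats),
                            plan = plan),
              variance = variance, tumor = isTRUE(tumor),
              seed = as.integer(seed))
  # a variance component at a level with a single unit cannot be estimated
  lvl <- c(withinSession = repeats, betweenSession = sessions,
           betweenScanner = scanners, betweenParticipant = participants)
  for (nm in names(lvl))
    if (cfg$variance[[nm]] > 0 && lvl[[nm]] == 1L)
      warning(sprintf("%s CV > 0 but only one %s unit: component not estimable",
                      nm, sub("between|within", "", nm)))
  structure(cfg, class = "phantomConfig")
}

# The scans of the design, in deterministic generation order.
scanPlan <- function(design) {
  g <- expand.grid(repeat. = seq_len(design$repeats),
                   session = seq_len(design$sessions),
                   scanner = LETTERS[seq_len(design$scanners)],
                   participant = sprintf("P%02d", seq_len(design$participants)),
                   stringsAsFactors = FALSE)
  g <- g[, c("participant", "scanner", "session", "repeat.")]
  if (design$plan == "minimal") {
    keep <- (g$scanner == "A" & g$session == 1L) |
            (g$scanner == "A" & g$session == 2L & g$repeat. == 1L) |
            (g$scanner == "B" & g$session == 1L & g$repeat. == 1L)
    g <- g[keep, , drop = FALSE]
  }
  g$scan <- sprintf("%s_%s_s%d_r%d", g$participant, g$scanner, g$session, g$repeat.)
  rownames(g) <- NULL
  g
}

#' Generate a synthetic multi-scan CEST dataset with ground truth
#'
#' Simulates one raw saturation-image volume per scan of the configured
#' reproducibility design. The noiseless voxel spectrum is the Lorentzian
#' superposition \eqn{b - \sum_p L(\Delta\omega - b_0(v); p)} (pool centers
#' appear shifted by the local field offset \eqn{b_0}), scaled by the tissue
#' reference intensity; zero-mean Gaussian noise of sd
#' \code{noiseSd * refIntensity} is added to every frame (negative
#' intensities are clipped at zero, as in magnitude images). Pool amplitudes
#' are perturbed multiplicatively (lognormal, ln-sd = CV) at the
#' participant, scanner, session and scan level. Identical configurations
#' (including the seed) produce bit-identical datasets.
#'
#' @param config a [phantomConfig()].
#' @return a [CestDataset-class]; realized pool parameters are in
#'   \code{truth} (see [truthSummary()]) and the simulated field in
#'   \code{b0Field}.
#' @export
#' @examples
#' cfg <- phantomConfig(gridShape = c(12L, 12L, 1L), participants = 1L,
#'                      scanners = 1L, sessions = 1L, repeats = 1L,
#'                      noiseSd = 0, b0Field = b0FieldSpec("constant", 0),
#'                      variance = varianceComponents(0, 0, 0, 0))
#' ds <- generateDataset(cfg)
#' ds
generateDataset <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  d <- config$gridShape
  sched <- config$schedule
  labels <- concentricLayout(d, tumor = config$tumor)
  present <- intersect(names(config$tissues), unique(as.vector(labels)))
  masks <- lapply(stats::setNames(nm = present), function(t) labels == t)

  b0 <- buildB0Field(config$b0Field, d)

  plan <- scanPlan(config$design)
  vc <- config$variance
  tissuePools <- lapply(config$tissues[present], function(t)
    names(t$pools))

  lnFactor <- function(cv, n) if (cv > 0) stats::rlnorm(n, 0, cv) else rep(1, n)

  # Hierarchical multiplicative perturbation factors, drawn level by level in
  # a fixed order so the dataset is seed-reproducible.
  drawLevel <- function(units, cv) {
    out <- list()
    for (u in units) {
      out[[u]] <- lapply(tissuePools, function(pls)
        stats::setNames(lnFactor(cv, length(pls)), pls))
    }
    out
  }
  des <- config$design
  pIds <- sprintf("P%02d", seq_len(des$participants))
  fP <- drawLevel(pIds, vc$betweenParticipant)
  scUnits <- as.vector(outer(pIds, LETTERS[seq_len(des$scanners)], paste, sep = "|"))
  fSc <- drawLevel(scUnits, vc$betweenScanner)
  seUnits <- as.vector(outer(scUnits, seq_len(des$sessions), paste, sep = "|"))
  fSe <- drawLevel(seUnits, vc$betweenSession)
  reUnits <- as.vector(outer(seUnits, seq_len(des$repeats), paste, sep = "|"))
  fRe <- drawLevel(reUnits, vc$withinSession)

  vox <- lapply(masks, which)
  nSat <- length(sched@offsets)
  nRef <- sched@nReferenceImages
  nFrames <- nRef + nSat

  scans <- vector("list", nrow(plan))
  truthRows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sc <- plan[i, ]
    vol <- array(0, c(d, nFrames))
    rows <- list()
    for (t in present) {
      tis <- config$tissues[[t]]
      idx <- vox[[t]]
      if (!length(idx)) next
      b0v <- b0[idx]
      spec <- matrix(tis$baseline, length(idx), nFrames)
      for (pl in names(tis$pools)) {
        p <- tis$pools[[pl]]
        amp <- p$amplitude *
          fP[[sc$participant]][[t]][[pl]] *
          fSc[[paste(sc$participant, sc$scanner, sep = "|")]][[t]][[pl]] *
          fSe[[paste(sc$participant, sc$scanner, sc$session, sep = "|")]][[t]][[pl]] *
          fRe[[paste(sc$participant, sc$scanner, sc$session, sc$repeat., sep = "|")]][[t]][[pl]]
        # saturation frames at scheduled offsets, then reference frames at
        # the placeholder offset; pool centers appear shifted by +b0
        for (k in seq_len(nSat))
          spec[, nRef + k] <- spec[, nRef + k] -
            lorentzianSafe(sched@offsets[k] - b0v, amp, p$center, p$fwhm)
        for (k in seq_len(nRef))
          spec[, k] <- spec[, k] -
            lorentzianSafe(sched@referenceOffset - b0v, amp, p$center, p$fwhm)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = sc$participant, scanner = sc$scanner,
          session = sc$session, repeat. = sc$repeat., scan = sc$scan,
          tissue = t, pool = pl, nominal = p$amplitude, realized = amp,
          stringsAsFactors = FALSE)
      }
      # realized amplitudes can transiently exceed the baseline under level
      # perturbations; the magnitude signal floors at zero
      sig <- tis$refIntensity * pmax(spec, 0)
      flat <- matrix(vol, prod(d), nFrames)
      flat[idx, ] <- sig
      vol <- array(flat, c(d, nFrames))
    }
    if (config$noiseSd > 0) {
      refI <- array(0, d)
      for (t in present) refI[vox[[t]]] <- config$tissues[[t]]$refIntensity
      noise <- array(stats::rnorm(prod(d) * nFrames, 0,
                                  rep(pmax(config$noiseSd * as.vector(refI), 1e-12),
                                      nFrames)),
                     c(d, nFrames))
      vol <- pmax(vol + noise, 0)
    }
    scans[[i]] <- new("RawCestVolume", data = vol, schedule = sched,
                      voxelSize = c(1.7, 1.7, 3),
                      provenance = list(participant = sc$participant,
                                        scanner = sc$scanner,
                                        session = sc$session,
                                        repeat. = sc$repeat.))
    truthRows[[i]] <- do.call(rbind, rows)
  }
  names(scans) <- plan$scan
  new("CestDataset", scans = scans, masks = masks,
      truth = do.call(rbind, truthRows), b0Field = b0,
      manifest = plan, config = unclass(config))
}

#' Realized per-scan, per-tissue pool amplitudes of a synthetic dataset
#'
#' One row per (participant, scanner, session, repeat, tissue, pool), with
#' the nominal amplitude and the realized amplitude (nominal times the
#' product of the level perturbations) exactly as used in the forward model.
#'
#' @param dataset a [CestDataset-class].
#' @return data.frame.
#' @export
truthSummary <- function(dataset) {
  stopifnot(is(dataset, "CestDataset"))
  dataset@truth
}
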