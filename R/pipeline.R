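#' Quantification options for the APT pipeline
#'
#' Surfaces every tunable of the quantification chain with the defaults
#' documented in the individual steps.
#'
#' @param fitRegion offset predicate for [fitTwoPoolVolume()].
#' @param fitControl start values and bounds, see [twoPoolFitControl()].
#' @param b0GridStep,b0SearchRange,b0MaxShift see [computeB0Map()].
#' @param target,zFloor see [computeMetricMaps()].
#' @param referenceSelection see [normalizeZSpectra()].
#' @return list of options.
#' @export
quantifyOptions <- function(fitRegion = defaultFitRegion(),
                            fitControl = twoPoolFitControl(),
                            b0GridStep = 0.01, b0SearchRange = c(-2, 2),
                            b0MaxShift = 1, target = 3.5, zFloor = 0.05,
                            referenceSelection = NULL) {
  list(fitRegion = fitRegion, fitControl = fitControl,
       b0GridStep = b0GridStep, b0SearchRange = b0SearchRange,
       b0MaxShift = b0MaxShift, target = target, zFloor = zFloor,
       referenceSelection = referenceSelection)
}

quantifyScan <- function(raw, opts) {
  z <- normalizeZSpectra(raw, referenceSelection = opts$referenceSelection)
  fit <- fitTwoPoolVolume(z, fitRegion = opts$fitRegion,
                          control = opts$fitControl)
  b0 <- computeB0Map(fit, gridStep = opts$b0GridStep,
                     searchRange = opts$b0SearchRange,
                     maxShift = opts$b0MaxShift)
  zc <- applyB0Correction(z, b0)
  maps <- computeMetricMaps(zc, fit, b0, target = opts$target,
                            zFloor = opts$zFloor)
  list(maps = maps, fit = fit, b0 = b0, zCorrected = zc,
       provenance = raw@provenance)
}

#' Run the quantification chain on every scan
#'
#' normalize -> two-pool fit -> B0 map -> B0 correction -> LD / MTRasym /
#' MTRrex, per scan. Deterministic given inputs and options. A failing scan
#' is reported (with provenance) in the log and the pipeline continues with
#' the remaining scans.
#'
#' @param x a [CestDataset-class], or a (named) list of
#'   [RawCestVolume-class] scans.
#' @param opts options from [quantifyOptions()].
#' @return list with \code{results} (per scan: \code{maps}, \code{fit},
#'   \code{b0}, \code{zCorrected}, \code{provenance}, or \code{error}) and
#'   \code{log} (per-scan data.frame of voxel counts: valid reference,
#'   converged fits, valid B0, valid metrics).
#' @export
runQuantify <- function(x, opts = quantifyOptions()) {
  scans <- if (is(x, "CestDataset")) x@scans else x
  if (is.null(names(scans)))
    names(scans) <- sprintf("scan%03d", seq_along(scans))
  results <- vector("list", length(scans))
  names(results) <- names(scans)
  logRows <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    id <- names(scans)[i]
    res <- tryCatch(quantifyScan(scans[[i]], opts), error = function(e)
      list(error = conditionMessage(e), provenance = scans[[i]]@provenance))
    results[[i]] <- res
    logRows[[i]] <- if (is.null(res$error)) data.frame(
      scan = id,
      nValidReference = sum(res$zCorrected@validMask),
      nConverged = sum(res$fit@converged),
      nValidB0 = sum(res$b0@valid),
      nValidMetrics = sum(res$maps@valid),
      error = NA_character_, stringsAsFactors = FALSE)
    else data.frame(scan = id, nValidReference = NA_integer_,
                    nConverged = NA_integer_, nValidB0 = NA_integer_,
                    nValidMetrics = NA_integer_, error = res$error,
                    stringsAsFactors = FALSE)
  }
  list(results = results, log = do.call(rbind, logRows))
}

#' Run the full synthetic reproducibility study
#'
#' Generates the configured phantom dataset, quantifies every scan,
#' tabulates ROI averages, and computes the complete reproducibility
#' battery: per-level COV summaries (median [Q1-Q3] across participants),
#' Bland-Altman agreement per level, and mixed-effects tests per condition,
#' for every ROI and metric. The report embeds the generating configuration
#' and seed; identical configurations reproduce it exactly.
#'
#' @param config a [phantomConfig()].
#' @param opts quantification options, see [quantifyOptions()].
#' @param levels COV levels to summarize.
#' @param conditions design conditions for the mixed-effects tests.
#' @param rois ROI labels (default: all non-background masks).
#' @param metrics metric names.
#' @param selection level scan-selection rules.
#' @param alpha significance level.
#' @return list of class \code{"CestStudyReport"}: \code{table},
#'   \code{covSummaries} (data.frame), \code{covDetails} (list of
#'   [covByLevel()] results), \code{blandAltman} (named list),
#'   \code{mixedModels} (data.frame), \code{log}, \code{seed},
#'   \code{config}.
#' @export
runStudy <- function(config,
                     opts = quantifyOptions(),
                     levels = c("within_session", "between_session",
                                "between_scanner", "all_sessions"),
                     conditions = c("within_session", "between_session",
                                    "between_scanner"),
                     rois = NULL, metrics = c("LD", "MTRasym", "MTRrex"),
                     selection = defaultLevelSelection(), alpha = 0.05) {
  ds <- generateDataset(config)
  q <- runQuantify(ds, opts)
  tab <- buildReproTable(q, ds@masks, metrics = metrics)
  if (is.null(rois)) rois <- setdiff(names(ds@masks), "background")
  rois <- intersect(rois, unique(tab$roi))

  des <- config$design
  levels <- levels[vapply(levels, function(l) switch(l,
    within_session = des$repeats >= 2L,
    between_session = des$sessions >= 2L,
    between_scanner = des$scanners >= 2L,
    all_sessions = TRUE), TRUE)]
  conditions <- intersect(conditions, levels)

  covDetails <- list(); covRows <- list(); baList <- list(); mmRows <- list()
  for (roi in rois) for (m in metrics) {
    for (lv in levels) {
      cs <- covByLevel(tab, lv, roi, m, selection)
      covDetails[[paste(lv, roi, m, sep = ".")]] <- cs
      covRows[[length(covRows) + 1L]] <- data.frame(
        level = lv, roi = roi, metric = m, n = cs$n,
        median = cs$median, q1 = cs$q1, q3 = cs$q3,
        stringsAsFactors = FALSE)
    }
    for (lv in setdiff(levels, "all_sessions")) {
      sub <- tab[tab$roi == roi & tab$metric == m, , drop = FALSE]
      sub <- sub[selection[[lv]](sub), , drop = FALSE]
      splitVar <- switch(lv, within_session = "repeat.",
                         between_session = "session",
                         between_scanner = "scanner")
      lvls <- sort(unique(sub[[splitVar]]))[1:2]
      a <- sub[sub[[splitVar]] == lvls[1], ]
      b <- sub[sub[[splitVar]] == lvls[2], ]
      common <- intersect(a$participant, b$participant)
      if (length(common) >= 2L)
        baList[[paste(lv, roi, m, sep = ".")]] <- blandAltman(
          a$value[match(common, a$participant)],
          b$value[match(common, b$participant)])
    }
    for (cd in conditions) {
      mm <- tryCatch(mixedEffectTest(tab, roi, m, cd, selection, alpha),
                     error = function(e) NULL)
      if (!is.null(mm))
        mmRows[[length(mmRows) + 1L]] <- data.frame(
          condition = cd, roi = roi, metric = m,
          estimate = mm$estimate, se = mm$se, pValue = mm$pValue,
          significant = mm$significant, n = mm$nParticipants,
          method = mm$method, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    table = tab,
    covSummaries = do.call(rbind, covRows),
    covDetails = covDetails,
    blandAltman = baList,
    mixedModels = if (length(mmRows)) do.call(rbind, mmRows) else NULL,
    log = q$log,
    seed = config$seed,
    config = unclass(config)),
    class = "CestStudyReport")
}

#' @export
print.CestStudyReport <- function(x, ...) {
  cat(sprintf("CEST reproducibility study report (seed %d)\n", x$seed))
  cat(sprintf("  %d scans quantified, %d ROI x metric x scan averages\n",
              nrow(x$log), nrow(x$table)))
  cat("  group median COV [Q1-Q3] (%):\n")
  s <- x$covSummaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-16s %-14s %-8s %5.2f [%.2f-%.2f] (N=%d)\n",
                s$level[i], s$roi[i], s$metric[i], s$median[i],
                s$q1[i], s$q3[i], s$n[i]))
  invisible(x)
}

#' Write a study report to disk
#'
#' The reproducibility table and COV summaries as TSV, the full report
#' (including Bland-Altman and mixed-model results and the configuration
#' echo) as JSON, and one Bland-Altman plot per level/ROI/metric as PNG.
#'
#' @param report a [runStudy()] result.
#' @param dir output directory.
#' @param plots logical, write Bland-Altman PNGs.
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(report, dir, plots = FALSE) {
  stopifnot(inherits(report, "CestStudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$table, file.path(dir, "repro_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$covSummaries, file.path(dir, "cov_summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ba <- lapply(report$blandAltman, function(b)
    b[c("bias", "sdDiff", "loaLow", "loaHigh")])
  cfg <- report$config
  cfg$tissues <- lapply(cfg$tissues, unclass)
  cfg$schedule <- list(offsets = cfg$schedule@offsets,
                       referenceOffset = cfg$schedule@referenceOffset,
                       nReferenceImages = cfg$schedule@nReferenceImages,
                       referenceSelection = cfg$schedule@referenceSelection)
  cfg$fitRegion <- NULL
  jsonlite::write_json(
    list(seed = report$seed,
         covSummaries = report$covSummaries,
         blandAltman = ba,
         mixedModels = report$mixedModels,
         log = report$log,
         config = cfg),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, na = "null")
  if (plots) {
    for (nm in names(report$blandAltman)) {
      grDevices::png(file.path(dir, paste0("bland_altman_", nm, ".png")),
                     width = 600, height = 500)
      plotBlandAltman(report$blandAltman[[nm]], main = nm)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
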