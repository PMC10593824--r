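#' ROI average of a metric map
#'
#' Mean over the voxels that are inside the mask and valid, with the
#' contributing voxel count. An ROI with zero contributing voxels yields an
#' explicit empty-ROI status and no number (mirroring real studies where a
#' small tumor mask can lose all voxels on the CEST grid), never an
#' exception.
#'
#' @param values 3D numeric array (e.g. one plane of [MetricMaps-class]).
#' @param mask logical 3D array on the same grid.
#' @param valid optional logical 3D validity array; defaults to finite
#'   values.
#' @return list with \code{value} (NA when empty), \code{nVoxels},
#'   \code{status} ("ok" or "empty ROI").
#' @export
roiMean <- function(values, mask, valid = NULL) {
  if (!identical(dim(values), dim(mask)))
    stop(sprintf("mask grid %s does not match map grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(values), collapse = "x")))
  use <- mask & is.finite(values)
  if (!is.null(valid)) use <- use & valid
  n <- sum(use)
  if (n == 0L)
    return(list(value = NA_real_, nVoxels = 0L, status = "empty ROI"))
  list(value = mean(values[use]), nVoxels = n, status = "ok")
}

#' Within-subject coefficient of variation
#'
#' \eqn{100 \cdot sd(x) / |mean(x)|} with the sample (n-1) standard
#' deviation; for two measurements this equals
#' \eqn{100 \cdot |x_1 - x_2| / (\sqrt{2}\,|\bar x|)}. Invariant under
#' positive rescaling and permutation of its inputs. Fewer than two finite
#' values, or a zero mean, are flagged by returning NA with a reason
#' attribute.
#'
#' @param values numeric vector of repeated measurements.
#' @return COV in percent, or NA with attribute \code{reason}.
#' @export
#' @examples
#' covWithin(c(10, 10))  # 0
#' covWithin(c(9, 11))   # 14.142...
covWithin <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2L)
    return(structure(NA_real_, reason = "fewer than 2 finite values"))
  m <- mean(x)
  if (m == 0)
    return(structure(NA_real_, reason = "zero mean"))
  100 * stats::sd(x) / abs(m)
}

#' Scan selections defining the reproducibility levels
#'
#' Which scans of the crossed design enter each COV level, mirroring the
#' three-level repeatability/reproducibility design: within-session uses the
#' two repeats of session 1 on scanner A; between-session uses repeat 1 of
#' sessions 1 and 2 on scanner A; between-scanner uses repeat 1 of session 1
#' on scanners A and B; all-sessions uses every scan. Each entry is a
#' filter \code{function(manifest-like data.frame) -> logical}.
#'
#' @return named list of filter functions.
#' @export
defaultLevelSelection <- function() {
  list(
    within_session  = function(d) d$scanner == "A" & d$session == 1L,
    between_session = function(d) d$scanner == "A" & d$repeat. == 1L,
    between_scanner = function(d) d$session == 1L & d$repeat. == 1L,
    all_sessions    = function(d) rep(TRUE, nrow(d))
  )
}

# Number of scans each level requires per participant.
levelScanCounts <- c(within_session = 2L, between_session = 2L,
                     between_scanner = 2L, all_sessions = 2L)

#' Build the tidy reproducibility table from quantified scans
#'
#' One row per (participant, scanner, session, repeat, ROI, metric) holding
#' the ROI-averaged metric value in percent. Empty ROIs are dropped from the
#' table and logged in the \code{"excluded"} attribute with their reason.
#'
#' @param quantified result of [runQuantify()] (its \code{results} element
#'   is also accepted).
#' @param masks named list of logical ROI masks.
#' @param metrics metric names to tabulate.
#' @return data.frame with attribute \code{excluded}.
#' @export
buildReproTable <- function(quantified, masks,
                            metrics = c("LD", "MTRasym", "MTRrex")) {
  results <- if (!is.null(quantified$results)) quantified$results else quantified
  rows <- list(); excluded <- list()
  for (id in names(results)) {
    res <- results[[id]]
    if (!is.null(res$error)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        scan = id, roi = NA_character_, metric = NA_character_,
        reason = res$error, stringsAsFactors = FALSE)
      next
    }
    prov <- res$provenance
    for (roi in names(masks)) {
      for (m in metrics) {
        rm <- roiMean(metricMap(res$maps, m), masks[[roi]],
                      validMask(res$maps))
        if (rm$status != "ok") {
          excluded[[length(excluded) + 1L]] <- data.frame(
            scan = id, roi = roi, metric = m, reason = rm$status,
            stringsAsFactors = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant = prov$participant, scanner = prov$scanner,
          session = prov$session, repeat. = prov$repeat.,
          roi = roi, metric = m, value = rm$value, nVoxels = rm$nVoxels,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(), scanner = character(),
               session = integer(), repeat. = integer(), roi = character(),
               metric = character(), value = numeric(), nVoxels = integer())
  key <- with(tab, paste(participant, scanner, session, repeat., roi, metric))
  if (anyDuplicated(key)) stop("duplicate (scan, roi, metric) rows")
  attr(tab, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else NULL
  tab
}

#' Per-participant COV summary at one reproducibility level
#'
#' Selects the level's scans (see [defaultLevelSelection()]), computes the
#' within-subject COV per participant via [covWithin()], and summarizes the
#' group as median and interquartile range (linear-interpolation quantiles).
#' Participants missing a required scan, or with an undefined COV, are
#' excluded with a logged reason.
#'
#' @param table reproducibility table from [buildReproTable()].
#' @param level one of \code{within_session, between_session,
#'   between_scanner, all_sessions}.
#' @param roi ROI label.
#' @param metric metric name.
#' @param selection list of level filters, default
#'   [defaultLevelSelection()].
#' @return list of class \code{"CovSummary"}: \code{level, roi, metric,
#'   perParticipant} (named vector, percent), \code{median, q1, q3, n,
#'   excluded}.
#' @export
covByLevel <- function(table, level = c("within_session", "between_session",
                                        "between_scanner", "all_sessions"),
                       roi, metric, selection = defaultLevelSelection()) {
  level <- match.arg(level)
  sub <- table[table$roi == roi & table$metric == metric, , drop = FALSE]
  sub <- sub[selection[[level]](sub), , drop = FALSE]
  need <- levelScanCounts[[level]]
  covs <- c(); excluded <- list()
  for (p in unique(sub$participant)) {
    v <- sub$value[sub$participant == p]
    if (length(v) < need) {
      excluded[[p]] <- sprintf("only %d of %d required scans", length(v), need)
      next
    }
    cv <- covWithin(v)
    if (is.na(cv)) {
      excluded[[p]] <- attr(cv, "reason")
      next
    }
    covs[p] <- cv
  }
  q <- if (length(covs)) stats::quantile(covs, c(0.25, 0.5, 0.75), type = 7,
                                         names = FALSE)
       else rep(NA_real_, 3)
  structure(list(level = level, roi = roi, metric = metric,
                 perParticipant = covs, median = q[2], q1 = q[1], q3 = q[3],
                 n = length(covs), excluded = excluded),
            class = "CovSummary")
}

#' @export
print.CovSummary <- function(x, ...) {
  cat(sprintf("COV of %s in %s, %s (N = %d): median %.2f%% [%.2f-%.2f]\n",
              x$metric, x$roi, gsub("_", " ", x$level), x$n,
              x$median, x$q1, x$q3))
  if (length(x$excluded))
    cat(sprintf("  excluded: %s\n",
                paste(names(x$excluded), unlist(x$excluded),
                      sep = ": ", collapse = "; ")))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements per participant: differences \eqn{d = m_1 - m_2}
#' against means \eqn{(m_1 + m_2)/2}; bias = mean(d), sd_diff = sample sd of
#' d, limits of agreement = bias +/- 1.96 sd_diff. Swapping the pair order
#' flips the bias sign and leaves the limit width unchanged.
#'
#' @param m1,m2 numeric vectors of the first and second measurement.
#' @return list of class \code{"BlandAltman"}: \code{bias, sdDiff, loaLow,
#'   loaHigh, pairs} (data.frame of mean/difference, retained for
#'   plotting).
#' @export
blandAltman <- function(m1, m2) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- m1 - m2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sdDiff = s,
                 loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
                 pairs = data.frame(mean = (m1 + m2) / 2, difference = d)),
            class = "BlandAltman")
}

#' @export
print.BlandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f]\n",
              nrow(x$pairs), x$bias, x$loaLow, x$loaHigh))
  invisible(x)
}

#' Bland-Altman scatter with bias and limits of agreement
#'
#' @param x a [blandAltman()] result.
#' @param main plot title.
#' @param ... forwarded to [graphics::plot()].
#' @export
plotBlandAltman <- function(x, main = "Bland-Altman", ...) {
  stopifnot(inherits(x, "BlandAltman"))
  graphics::plot(x$pairs$mean, x$pairs$difference,
                 xlab = "mean of measurements (%)",
                 ylab = "difference (%)", main = main, pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loaLow, x$loaHigh), lty = 2)
  invisible(x)
}

#' Mixed-effects test of a design condition
#'
#' Fits \code{value ~ condition + (1 | participant)} by maximum likelihood
#' on the two scans the condition compares (repeat 1 vs 2 within session;
#' session 1 vs 2 between sessions; scanner A vs B between scanners) and
#' tests the condition term by a likelihood-ratio test against the model
#' without it. A singular fit (zero estimated between-participant variance)
#' falls back to a fixed-effects model with participant as a fixed blocking
#' factor, flagged in the result.
#'
#' @param table reproducibility table from [buildReproTable()].
#' @param roi ROI label.
#' @param metric metric name.
#' @param condition design factor to test.
#' @param selection list of level filters, default
#'   [defaultLevelSelection()].
#' @param alpha significance level used for the reported decision.
#' @return list of class \code{"MixedModelResult"}: \code{estimate}
#'   (condition effect, percent), \code{se}, \code{pValue},
#'   \code{significant}, \code{nParticipants}, \code{converged},
#'   \code{method} ("lmm" or "fixed-fallback").
#' @export
mixedEffectTest <- function(table, roi, metric,
                            condition = c("within_session", "between_session",
                                          "between_scanner"),
                            selection = defaultLevelSelection(),
                            alpha = 0.05) {
  condition <- match.arg(condition)
  sub <- table[table$roi == roi & table$metric == metric, , drop = FALSE]
  sub <- sub[selection[[condition]](sub), , drop = FALSE]
  condVar <- switch(condition, within_session = "repeat.",
                    between_session = "session", between_scanner = "scanner")
  sub$cond <- factor(sub[[condVar]])
  keep <- stats::ave(seq_len(nrow(sub)), sub$participant,
                     FUN = length) == nlevels(sub$cond)
  sub <- sub[keep, , drop = FALSE]
  nP <- length(unique(sub$participant))
  if (nlevels(droplevels(sub$cond)) < 2L)
    stop("condition has fewer than 2 levels after selection")
  if (nP < 4L) stop("need at least 4 participants with complete scans")
  sub$participant <- factor(sub$participant)

  if (stats::var(sub$value) == 0) {
    return(structure(list(estimate = 0, se = 0, pValue = 1,
                          significant = FALSE, nParticipants = nP,
                          converged = TRUE, method = "degenerate"),
                     class = "MixedModelResult"))
  }
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ cond + (1 | participant), data = sub, REML = FALSE)))
  singular <- lme4::isSingular(full, tol = 1e-6)
  if (!singular) {
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ (1 | participant), data = sub, REML = FALSE)))
    lrt <- stats::anova(null, full)
    p <- lrt[2, "Pr(>Chisq)"]
    co <- summary(full)$coefficients
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    method <- "lmm"
    conv <- is.null(full@optinfo$conv$lme4$messages)
  } else {
    fullF <- stats::lm(value ~ participant + cond, data = sub)
    nullF <- stats::lm(value ~ participant, data = sub)
    a <- stats::anova(nullF, fullF)
    p <- a[2, "Pr(>F)"]
    co <- summary(fullF)$coefficients
    i <- grep("^cond", rownames(co))[1]
    est <- co[i, "Estimate"]; se <- co[i, "Std. Error"]
    method <- "fixed-fallback"
    conv <- TRUE
  }
  structure(list(estimate = est, se = se, pValue = p,
                 significant = is.finite(p) && p < alpha,
                 nParticipants = nP, converged = conv, method = method),
            class = "MixedModelResult")
}

#' @export
print.MixedModelResult <- function(x, ...) {
  cat(sprintf("Mixed-effects test (%s, N = %d): effect %.4f +/- %.4f, p = %.4g%s\n",
              x$method, x$nParticipants, x$estimate, x$se, x$pValue,
              if (x$significant) " *" else ""))
  invisible(x)
}
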