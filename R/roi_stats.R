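## ROI-level statistics: site selection, studentized-bootstrap confidence
## bands, run-length significance and distance-from-calcarine shell profiles.

#' Select analysis sites and retained ROIs
#'
#' Removes excluded sites (seizure-onset zone, interictal spikes, MRI lesion,
#' artefact) and drops (hemisphere, ROI) groups with fewer than
#' \code{minSites} clean sites from ROI-level statistics; their sites remain
#' available for shell profiles.
#'
#' @param channels channel metadata data.frame (see \code{\link{Recording}}).
#' @param minSites minimum clean sites per ROI (default 4).
#' @return list(sites = clean iEEG channel rows, rois = data.frame(roi,
#'   hemisphere, n_sites) of retained ROIs).
#' @export
selectAnalysisSites <- function(channels, minSites = 4) {
  if (!is.data.frame(channels) || !nrow(channels))
    stop("empty electrode table")
  sites <- channels[channels$type == "ieeg" & !channels$excluded, ,
                    drop = FALSE]
  key <- paste(sites$hemisphere, sites$roi, sep = "\r")
  n <- table(key)
  keepKey <- names(n)[n >= minSites]
  parts <- strsplit(keepKey, "\r", fixed = TRUE)
  rois <- data.frame(
    hemisphere = vapply(parts, `[[`, "", 1L),
    roi = vapply(parts, `[[`, "", 2L),
    n_sites = as.integer(n[keepKey]), stringsAsFactors = FALSE)
  rois <- rois[order(rois$hemisphere, rois$roi), , drop = FALSE]
  rownames(rois) <- NULL
  list(sites = sites, rois = rois)
}

#' Studentized (bootstrap-t) confidence interval
#'
#' Resamples the values with replacement, forms the pivot
#' t* = (mean* - mean) / se* with the analytic standard error of each
#' resample, and inverts its quantiles: CI = mean - q(t*) se. Identical
#' values give the degenerate interval lower = upper = mean.
#'
#' @param values numeric vector (e.g. per-site percent change), length >= 2.
#' @param level confidence level (default 0.9999).
#' @param nResamples bootstrap resamples (default 10000).
#' @param seed integer seed for reproducibility.
#' @return named numeric c(mean, lower, upper).
#' @export
studentizedBootstrap <- function(values, level = 0.9999, nResamples = 10000,
                                 seed = 1) {
  stopifnot(length(values) >= 2, level > 0, level < 1, nResamples >= 1)
  ci <- bootstrapCISeries(matrix(values, ncol = 1), level = level,
                          nResamples = nResamples, seed = seed)
  c(mean = ci$mean[1], lower = ci$lower[1], upper = ci$upper[1])
}

#' Studentized-bootstrap bands for a sites-by-bins matrix
#'
#' Vectorised bootstrap-t over every column (time bin) of a sites x bins
#' matrix, resampling whole sites so one resample set serves all bins.
#'
#' @param mat numeric matrix, sites x bins.
#' @param level confidence level.
#' @param nResamples bootstrap resamples.
#' @param seed integer seed.
#' @return list(mean, lower, upper), each a length-ncol(mat) vector.
#' @export
bootstrapCISeries <- function(mat, level = 0.9999, nResamples = 10000,
                              seed = 1) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1)
  n <- nrow(mat)
  m <- colMeans(mat)
  if (n == 1L)                       # single site: no spread to resample
    return(list(mean = m, lower = m, upper = m))
  s <- apply(mat, 2, sd)
  se <- s / sqrt(n)
  set.seed(seed)
  B <- as.integer(nResamples)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  W <- matrix(0, B, n)               # resample weight matrix (counts / n)
  for (j in seq_len(n)) {
    ii <- cbind(seq_len(B), idx[, j])
    W[ii] <- W[ii] + 1
  }
  W <- W / n
  bm <- W %*% mat
  bv <- (W %*% (mat * mat) - bm * bm) * n / (n - 1)
  bse <- sqrt(pmax(bv, 0) / n)
  tstar <- (bm - rep(m, each = B)) / bse
  tstar[bse == 0] <- 0
  alpha <- 1 - level
  qlo <- apply(tstar, 2, quantile, probs = alpha / 2, names = FALSE)
  qhi <- apply(tstar, 2, quantile, probs = 1 - alpha / 2, names = FALSE)
  lower <- m - qhi * se
  upper <- m - qlo * se
  deg <- se == 0
  lower[deg] <- m[deg]; upper[deg] <- m[deg]
  list(mean = m, lower = pmin(lower, m), upper = pmax(upper, m))
}

#' Run-length significance masks and onset latency
#'
#' Augmentation requires the lower CI bound above 0 for at least
#' \code{minRun} consecutive bins (attenuation: upper bound below 0); runs
#' shorter than \code{minRun} are discarded entirely. The onset latency is
#' the centre time of the first bin of the earliest surviving run.
#'
#' @param lower,upper CI bound vectors on the analysis grid.
#' @param timesMs bin-centre times.
#' @param minRun minimum consecutive bins (default 8).
#' @return list(aug, att) logical masks plus \code{onsetAugMs},
#'   \code{onsetAttMs} (NA when no run survives).
#' @export
detectSignificantRuns <- function(lower, upper, timesMs, minRun = 8) {
  stopifnot(length(lower) == length(upper),
            length(lower) == length(timesMs))
  runMask <- function(flag) {
    r <- rle(flag)
    r$values <- r$values & r$lengths >= minRun
    inverse.rle(r)
  }
  aug <- runMask(lower > 0)
  att <- runMask(upper < 0)
  list(aug = aug, att = att,
       onsetAugMs = if (any(aug)) timesMs[which(aug)[1]] else NA_real_,
       onsetAttMs = if (any(att)) timesMs[which(att)[1]] else NA_real_)
}

#' Per-ROI bootstrap series over the analysis window
#'
#' For every retained (hemisphere, ROI) the per-site percent-change rows of
#' \code{pcm} are reduced to a studentized-bootstrap mean with CI bounds per
#' analysis bin, and run-length significance masks with onset latencies.
#'
#' @param pcm a \code{\link{PercentChangeMap}}.
#' @param channels channel metadata of the recording.
#' @param level CI level (default 0.9999, the 99.99\% CI equivalent to a
#'   Bonferroni correction over 500 comparisons).
#' @param nResamples bootstrap resamples.
#' @param minRun minimum consecutive significant bins (default 8).
#' @param minSites minimum sites per ROI (default 4).
#' @param seed integer seed; per-ROI seeds are derived from it.
#' @return A \code{\link{ROISeries}}.
#' @export
computeRoiSeries <- function(pcm, channels, level = 0.9999,
                             nResamples = 10000, minRun = 8, minSites = 4,
                             seed = 1) {
  stopifnot(is(pcm, "PercentChangeMap"))
  sel <- selectAnalysisSites(channels, minSites)
  times <- binTimes(pcm)
  aIdx <- which(times >= pcm@analysisMs[1] & times <= pcm@analysisMs[2])
  tbl <- list(); ons <- list()
  for (r in seq_len(nrow(sel$rois))) {
    hemi <- sel$rois$hemisphere[r]; roi <- sel$rois$roi[r]
    ids <- sel$sites$site_id[sel$sites$hemisphere == hemi &
                             sel$sites$roi == roi]
    ids <- intersect(ids, rownames(pctValues(pcm)))
    if (length(ids) < minSites) next
    mat <- pctValues(pcm)[ids, aIdx, drop = FALSE]
    ci <- bootstrapCISeries(mat, level = level, nResamples = nResamples,
                            seed = deriveSeed(seed, paste0(hemi, roi)))
    runs <- detectSignificantRuns(ci$lower, ci$upper, times[aIdx], minRun)
    tbl[[length(tbl) + 1L]] <- data.frame(
      roi = roi, hemisphere = hemi, band = pcm@band, mark = pcm@mark,
      time_ms = times[aIdx], mean = ci$mean, lo = ci$lower, hi = ci$upper,
      sig_aug = runs$aug, sig_att = runs$att, n_sites = length(ids),
      stringsAsFactors = FALSE)
    ons[[length(ons) + 1L]] <- data.frame(
      roi = roi, hemisphere = hemi, band = pcm@band, mark = pcm@mark,
      onset_aug_ms = runs$onsetAugMs, onset_att_ms = runs$onsetAttMs,
      peak_pct = ci$mean[which.max(abs(ci$mean))],
      stringsAsFactors = FALSE)
  }
  if (!length(tbl)) stop("no ROI reached the minimum site count")
  new("ROISeries", table = do.call(rbind, tbl), onsets = do.call(rbind, ons),
      level = level, minRun = as.integer(minRun),
      nResamples = as.integer(nResamples))
}

#' Distance-from-calcarine shell profile on the flattened surface
#'
#' Interpolates per-site percent change to flat-map mesh points within
#' \code{interpRadius} of each electrode, then groups mesh points into
#' ventral/dorsal 10-mm distance shells from the calcarine sulcus. The
#' calcarine reference line is \code{flat_y_mm = 0}; ventral cortex has
#' negative, dorsal positive \code{flat_y_mm}, and distance is measured as
#' |flat_y_mm| (Euclidean in flat-map mm). Shells whose mesh points receive
#' no electrode within the radius are reported missing (NA), not zero.
#' Shell-level significance reuses the studentized bootstrap and run rule
#' over the shell's contributing electrodes (when at least two contribute).
#'
#' @param pcm a \code{\link{PercentChangeMap}}.
#' @param channels channel metadata with flat-map coordinates.
#' @param mesh data.frame(flat_x_mm, flat_y_mm) of analysis mesh points;
#'   NULL builds a regular 2-mm grid over the electrode bounding box.
#' @param interpRadius electrode-to-mesh interpolation radius, mm.
#' @param shellWidth shell width, mm (default 10).
#' @param level,nResamples,minRun,seed as in \code{\link{computeRoiSeries}}.
#' @return data.frame(shell, side, d_lo, d_hi, time_ms, value, n_electrodes,
#'   sig_aug, sig_att).
#' @export
distanceShellProfile <- function(pcm, channels, mesh = NULL,
                                 interpRadius = 10, shellWidth = 10,
                                 level = 0.9999, nResamples = 10000,
                                 minRun = 8, seed = 1) {
  stopifnot(is(pcm, "PercentChangeMap"))
  el <- channels[channels$type == "ieeg" & !channels$excluded &
                 is.finite(channels$flat_x_mm) & is.finite(channels$flat_y_mm), ,
                 drop = FALSE]
  el <- el[el$site_id %in% rownames(pctValues(pcm)), , drop = FALSE]
  if (!nrow(el)) stop("no electrodes with flat-map coordinates")
  if (is.null(mesh)) {
    gx <- seq(min(el$flat_x_mm) - interpRadius,
              max(el$flat_x_mm) + interpRadius, by = 2)
    gy <- seq(min(el$flat_y_mm) - interpRadius,
              max(el$flat_y_mm) + interpRadius, by = 2)
    mesh <- expand.grid(flat_x_mm = gx, flat_y_mm = gy)
  }
  times <- binTimes(pcm)
  aIdx <- which(times >= pcm@analysisMs[1] & times <= pcm@analysisMs[2])
  pct <- pctValues(pcm)[el$site_id, aIdx, drop = FALSE]

  d2 <- outer(mesh$flat_x_mm, el$flat_x_mm, "-")^2 +
        outer(mesh$flat_y_mm, el$flat_y_mm, "-")^2
  within <- d2 <= interpRadius^2
  covered <- rowSums(within) > 0
  side <- ifelse(mesh$flat_y_mm < 0, "Ventral", "Dorsal")
  shellIdx <- floor(abs(mesh$flat_y_mm) / shellWidth)
  key <- paste(side, shellIdx)

  out <- list()
  for (k in unique(key)) {
    inShell <- key == k
    sd1 <- strsplit(k, " ")[[1]]
    dLo <- as.numeric(sd1[2]) * shellWidth
    lbl <- sprintf("%s_%d-%dmm", sd1[1], dLo, dLo + shellWidth)
    cov <- inShell & covered
    if (!any(cov)) {
      out[[length(out) + 1L]] <- data.frame(
        shell = lbl, side = sd1[1], d_lo = dLo, d_hi = dLo + shellWidth,
        time_ms = times[aIdx], value = NA_real_, n_electrodes = 0L,
        sig_aug = NA, sig_att = NA, stringsAsFactors = FALSE)
      next
    }
    ## mesh-point value = mean over electrodes within radius; shell value =
    ## mean over its covered mesh points
    w <- within[cov, , drop = FALSE]
    meshVals <- (w %*% pct) / rowSums(w)
    val <- colMeans(meshVals)
    contrib <- which(colSums(w) > 0)
    if (length(contrib) >= 2) {
      ci <- bootstrapCISeries(pct[contrib, , drop = FALSE], level = level,
                              nResamples = nResamples,
                              seed = deriveSeed(seed, k))
      runs <- detectSignificantRuns(ci$lower, ci$upper, times[aIdx], minRun)
      sa <- runs$aug; st <- runs$att
    } else {
      sa <- rep(NA, length(aIdx)); st <- rep(NA, length(aIdx))
    }
    out[[length(out) + 1L]] <- data.frame(
      shell = lbl, side = sd1[1], d_lo = dLo, d_hi = dLo + shellWidth,
      time_ms = times[aIdx], value = as.numeric(val),
      n_electrodes = length(contrib), sig_aug = sa, sig_att = st,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$side, res$d_lo, res$time_ms), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bonferroni comparison count equivalent to a CI level
#'
#' The number of repeated comparisons for which a per-comparison level
#' \code{1 - level} Bonferroni-corrects a family-wise alpha: employing a
#' 99.99\% CI corresponds to 0.05 / 0.0001 = 500 comparisons.
#'
#' @param level CI level (default 0.9999).
#' @param familyAlpha family-wise error rate (default 0.05).
#' @return number of comparisons.
#' @export
bonferroniComparisons <- function(level = 0.9999, familyAlpha = 0.05) {
  stopifnot(level > 0, level < 1)
  familyAlpha / (1 - level)
}
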