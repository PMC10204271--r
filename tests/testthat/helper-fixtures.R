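# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the analytic envelope uses the FFT
# analytic-signal construction, and the co-modulation oracle is a literal
# triple loop.

smallChannelTable <- function(sitesPerRoi = 2,
                              rois = c("lateral_occipital", "pericalcarine"))
  defaultChannelTable(sitesPerRoi = sitesPerRoi, rois = rois)

smallConfig <- function(nEvents = 4, sitesPerRoi = 2,
                        rois = c("lateral_occipital", "pericalcarine"),
                        profiles = defaultModulationProfiles(), seed = 1,
                        ...) {
  profiles <- profiles[profiles$roi %in% rois, , drop = FALSE]
  simConfig(nEventsPerKind = nEvents,
            channelTable = smallChannelTable(sitesPerRoi, rois),
            modulationProfiles = profiles, seed = seed, ...)
}

# FFT analytic-signal envelope (independent of the demodulation path)
analyticEnvelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# brute-force co-modulation scan: pairs x window starts x bins
bruteComod <- function(masks, timesMs, minRun = 8) {
  out <- list()
  nR <- nrow(masks); nT <- ncol(masks)
  for (i in seq_len(nR - 1)) for (j in (i + 1):nR) for (pol in c(1L, -1L)) {
    qualifying <- logical(nT)        # bins inside any qualifying window
    for (s in seq_len(nT - minRun + 1)) {
      ok <- TRUE
      for (b in s:(s + minRun - 1))
        if (masks[i, b] != pol || masks[j, b] != pol) { ok <- FALSE; break }
      if (ok) qualifying[s:(s + minRun - 1)] <- TRUE
    }
    r <- rle(qualifying)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (h in which(r$values))
      out[[length(out) + 1L]] <- data.frame(
        roi_a = rownames(masks)[i], roi_b = rownames(masks)[j],
        polarity = if (pol > 0) "co-augmentation" else "co-attenuation",
        t_start_ms = timesMs[starts[h]], t_end_ms = timesMs[ends[h]],
        n_bins = r$lengths[h], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(roi_a = character(), roi_b = character(),
                      polarity = character(), t_start_ms = numeric(),
                      t_end_ms = numeric(), n_bins = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$t_start_ms, res$roi_a, res$roi_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# constant-value percent-change map for geometry-level tests
constantPcm <- function(siteIds, values, band = "alpha",
                        mark = "closure_onset") {
  grid <- epochGrid(bandSpec(band)$binMs)
  pct <- matrix(rep(values, length(grid$centers)), nrow = length(siteIds),
                dimnames = list(siteIds, NULL))
  new("PercentChangeMap", pct = pct, band = band, mark = mark,
      timeMs = grid$centers, baselineMs = grid$baseline,
      analysisMs = grid$analysis, nTrials = 10L, droppedEvents = 0L)
}
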