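## Synthetic-data generator: event schedules, multichannel recordings with
## known injected band-amplitude modulations, and streamline fixtures.

## One global seed fans out to per-stage seeds so stages are individually
## reproducible; kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

#' Default electrode/EOG channel table
#'
#' Ten occipital/parietal ROIs (five per hemisphere) with \code{sitesPerRoi}
#' subdural sites each at 10 mm centre-to-centre spacing, plus one EOG
#' channel. Flat-map coordinates place the calcarine sulcus at
#' \code{flat_y_mm = 0}, ventral cortex at negative and dorsal at positive
#' \code{flat_y_mm}.
#'
#' @param sitesPerRoi electrode sites per ROI (default 4, the minimum a ROI
#'   needs to enter ROI-level statistics).
#' @param rois ROI labels to use per hemisphere.
#' @return data.frame suitable for the \code{channelTable} slot of
#'   \code{\link{simConfig}}.
#' @export
defaultChannelTable <- function(sitesPerRoi = 4,
                                rois = c("lateral_occipital", "pericalcarine",
                                         "lingual", "fusiform",
                                         "inferior_parietal")) {
  flatY <- c(lateral_occipital = 25, pericalcarine = -5, lingual = -20,
             fusiform = -40, inferior_parietal = 45)
  rows <- list()
  for (hemi in c("L", "R")) {
    for (ri in seq_along(rois)) {
      roi <- rois[ri]
      for (s in seq_len(sitesPerRoi)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sprintf("%s_%s_%02d", hemi, roi, s),
          patient_id = "sim01", roi = roi, hemisphere = hemi,
          type = "ieeg", excluded = FALSE, exclusion_reason = "",
          x_mm = (if (hemi == "L") -1 else 1) * (30 + 3 * ri),
          y_mm = -70 + 18 * ri + 10 * ((s - 1) %% 2),
          z_mm = -20 + 12 * ri + 10 * ((s - 1) %/% 2),
          flat_x_mm = (if (hemi == "L") -1 else 1) * (10 + 6 * ri) +
            3 * ((s - 1) %% 2),
          flat_y_mm = unname(flatY[roi]) + 3 * ((s - 1) %/% 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  eog <- data.frame(site_id = "EOG1", patient_id = "sim01", roi = "",
                    hemisphere = "", type = "eog", excluded = FALSE,
                    exclusion_reason = "", x_mm = 0, y_mm = 90, z_mm = -40,
                    flat_x_mm = NA_real_, flat_y_mm = NA_real_,
                    stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), eog)
}

#' Default injected modulation profiles
#'
#' Emulates the dominant occipital pattern: eye-closure alpha augmentation
#' (strongest in the lateral occipital region) with concurrent high-gamma
#' attenuation, and eye-opening-offset alpha attenuation with high-gamma
#' augmentation.
#'
#' @return data.frame with columns roi, band, kind, mark_edge, onset_ms,
#'   duration_ms, peak_pct, ramp_ms.
#' @export
defaultModulationProfiles <- function() {
  data.frame(
    roi = c("lateral_occipital", "pericalcarine",
            "lateral_occipital", "lateral_occipital", "pericalcarine"),
    band = c("alpha", "alpha", "high_gamma", "alpha", "high_gamma"),
    kind = c("closure", "closure", "closure", "opening", "opening"),
    mark_edge = c("onset", "onset", "onset", "offset", "offset"),
    onset_ms = c(50, 100, 50, 200, 100),
    duration_ms = c(1000, 900, 1000, 800, 600),
    peak_pct = c(50, 30, -15, -20, 25),
    ramp_ms = c(100, 100, 100, 100, 100),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults encode the emulated study conditions: 1000 Hz sampling, at least
#' 16 events per kind (default 20), log-normal event durations with median
#' 176/175 ms matched to the printed inter-quartile ranges (143-217 and
#' 128-215 ms), opposite-kind separation above 2 s, and a 100 microvolt EOG
#' deflection against sub-threshold background noise.
#'
#' @param samplingRate Hz.
#' @param nEventsPerKind scheduled events per kind.
#' @param closureDurMedianMs,openingDurMedianMs median movement durations (ms).
#' @param closureDurIqrMs,openingDurIqrMs duration IQRs (ms).
#' @param interEventGapS range of offset-to-onset gaps (s), minimum > 2.
#' @param channelTable see \code{\link{defaultChannelTable}}.
#' @param modulationProfiles see \code{\link{defaultModulationProfiles}}.
#' @param noiseUv 1/f background SD (microvolts).
#' @param alphaBaseUv baseline 10 Hz component amplitude.
#' @param gammaBaseUv baseline 70-110 Hz component amplitude.
#' @param eogDeflectionUv EOG deflection amplitude, must exceed 50.
#' @param eogNoiseUv EOG background SD.
#' @param durationS recording length (s); NA sizes it from the schedule.
#' @param seed integer master seed.
#' @return A validated \code{\link{SimConfig}}.
#' @export
simConfig <- function(samplingRate = 1000, nEventsPerKind = 20,
                      closureDurMedianMs = 176, openingDurMedianMs = 175,
                      closureDurIqrMs = c(143, 217),
                      openingDurIqrMs = c(128, 215),
                      interEventGapS = c(2.2, 3.0),
                      channelTable = defaultChannelTable(),
                      modulationProfiles = defaultModulationProfiles(),
                      noiseUv = 10, alphaBaseUv = 40, gammaBaseUv = 5,
                      eogDeflectionUv = 100, eogNoiseUv = 5,
                      durationS = NA_real_, seed = 1) {
  new("SimConfig", samplingRate = samplingRate,
      nEventsPerKind = nEventsPerKind,
      closureDurMedianMs = closureDurMedianMs,
      openingDurMedianMs = openingDurMedianMs,
      closureDurIqrMs = closureDurIqrMs, openingDurIqrMs = openingDurIqrMs,
      interEventGapS = interEventGapS, channelTable = channelTable,
      modulationProfiles = modulationProfiles, noiseUv = noiseUv,
      alphaBaseUv = alphaBaseUv, gammaBaseUv = gammaBaseUv,
      eogDeflectionUv = eogDeflectionUv, eogNoiseUv = eogNoiseUv,
      durationS = durationS, seed = seed)
}

## log-normal sigma matched to a printed IQR: q75/q25 = exp(2 z75 sigma)
.lnormSigma <- function(iqr) log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))

#' Schedule alternating eye-closure/eye-opening events
#'
#' Events alternate closure/opening with offset-to-onset gaps drawn from
#' \code{interEventGapS}, so every event's onset is more than 2 s away from
#' any opposite-kind event. Durations are log-normal draws matched to the
#' configured medians and IQRs. Deterministic under the configured seed.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return An \code{\link{EyeEventSet}} (times in ms).
#' @export
scheduleEvents <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- as.integer(config@nEventsPerKind)
  if (n == 0L)
    return(new("EyeEventSet",
               events = data.frame(kind = character(), onset_ms = numeric(),
                                   offset_ms = numeric()),
               insufficient = TRUE, minPerKind = 16))
  set.seed(deriveSeed(config@seed, "schedule"))
  durC <- rlnorm(n, log(config@closureDurMedianMs),
                 .lnormSigma(config@closureDurIqrMs))
  durO <- rlnorm(n, log(config@openingDurMedianMs),
                 .lnormSigma(config@openingDurIqrMs))
  gaps <- runif(2L * n - 1L, config@interEventGapS[1],
                config@interEventGapS[2]) * 1000
  kind <- rep(c("closure", "opening"), n)
  dur <- as.vector(rbind(durC, durO))
  onset <- numeric(2L * n)
  onset[1] <- 3000
  for (i in seq_len(2L * n - 1L))
    onset[i + 1L] <- onset[i] + dur[i] + gaps[i]
  offset <- onset + dur
  if (!is.na(config@durationS) &&
      (max(offset) + 3000) > config@durationS * 1000)
    stop(sprintf(paste("infeasible schedule: %d events per kind with > 2 s",
                       "opposite-kind separation need %.1f s but durationS is %.1f s"),
                 n, (max(offset) + 3000) / 1000, config@durationS))
  new("EyeEventSet",
      events = data.frame(kind = kind, onset_ms = onset, offset_ms = offset,
                          stringsAsFactors = FALSE),
      insufficient = n < 16L, minPerKind = 16)
}

## 1/f-amplitude-spectrum background noise, scaled to a target SD.
.onePerFNoise <- function(n, fs, sdUv, fMin = 0.5) {
  N <- nextn(n, 2)
  f <- (seq_len(N) - 1) * fs / N
  f <- pmin(f, fs - f)
  amp <- ifelse(f < fMin, 0, 1 / sqrt(f))
  x <- Re(fft(amp * exp(2i * pi * runif(N)), inverse = TRUE))[seq_len(n)]
  x * (sdUv / sd(x))
}

## flat-spectrum band-limited noise with a target RMS
.bandNoise <- function(n, fs, lo, hi, rmsUv) {
  N <- nextn(n, 2)
  f <- (seq_len(N) - 1) * fs / N
  f <- pmin(f, fs - f)
  amp <- as.numeric(f >= lo & f <= hi)
  x <- Re(fft(amp * exp(2i * pi * runif(N)), inverse = TRUE))[seq_len(n)]
  x * (rmsUv / sd(x))
}

## Raised-cosine envelope bump: the modulation starts at startMs, rises over
## rampMs, holds, and falls back to zero at endMs.
.bumpShape <- function(tMs, startMs, endMs, rampMs) {
  y <- numeric(length(tMs))
  y[tMs >= startMs + rampMs & tMs <= endMs - rampMs] <- 1
  up <- tMs > startMs & tMs < startMs + rampMs
  y[up] <- 0.5 * (1 - cos(pi * (tMs[up] - startMs) / rampMs))
  dn <- tMs > endMs - rampMs & tMs < endMs
  y[dn] <- 0.5 * (1 + cos(pi * (tMs[dn] - (endMs - rampMs)) / rampMs))
  y
}

.markTimes <- function(events, kind, edge) {
  ev <- events[events$kind == kind, , drop = FALSE]
  if (edge == "onset") ev$onset_ms else ev$offset_ms
}

#' Synthesize a multichannel iEEG + EOG recording with ground truth
#'
#' Each iEEG channel is 1/f background noise plus a 10 Hz alpha component and
#' a 70-110 Hz band-limited-noise high-gamma component whose envelopes follow
#' the channel's ROI modulation profiles around each event. The EOG channel
#' carries sub-threshold noise plus a monophasic deflection (positive for
#' closure, negative for opening) spanning each event. Ground truth records
#' the injected percent-change curves on the analysis grid; they are exactly
#' zero over the baseline window.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param events an \code{\link{EyeEventSet}}, typically from
#'   \code{\link{scheduleEvents}}.
#' @return list(recording = \code{\link{Recording}},
#'   truth = \code{\link{GroundTruth}}).
#' @export
synthesizeRecording <- function(config, events) {
  stopifnot(is(config, "SimConfig"), is(events, "EyeEventSet"))
  validObject(config)
  fs <- config@samplingRate
  ev <- eventTable(events)
  durMs <- if (!is.na(config@durationS)) config@durationS * 1000
           else if (nrow(ev)) max(ev$offset_ms) + 3000 else 10000
  nS <- as.integer(round(durMs / 1000 * fs))
  tMs <- (seq_len(nS) - 1) / fs * 1000
  tS <- tMs / 1000
  mp <- config@modulationProfiles
  ch <- config@channelTable

  ## per-(ROI, band) envelopes over the whole recording
  envFor <- function(roi, band) {
    env <- rep(1, nS)
    rows <- which(mp$roi == roi & mp$band == band)
    for (i in rows) {
      marks <- .markTimes(ev, mp$kind[i], mp$mark_edge[i])
      for (m in marks)
        env <- env + (mp$peak_pct[i] / 100) *
          .bumpShape(tMs, m + mp$onset_ms[i],
                     m + mp$onset_ms[i] + mp$duration_ms[i], mp$ramp_ms[i])
    }
    env
  }

  set.seed(deriveSeed(config@seed, "recording"))
  rois <- unique(ch$roi[ch$type == "ieeg"])
  envA <- lapply(setNames(rois, rois), envFor, band = "alpha")
  envG <- lapply(setNames(rois, rois), envFor, band = "high_gamma")

  sig <- matrix(0, nS, nrow(ch))
  colnames(sig) <- ch$site_id
  for (j in seq_len(nrow(ch))) {
    if (ch$type[j] == "eog") {
      x <- rnorm(nS, 0, config@eogNoiseUv)
      for (i in seq_len(nrow(ev))) {
        pol <- if (ev$kind[i] == "closure") 1 else -1
        d <- ev$offset_ms[i] - ev$onset_ms[i]
        rise <- min(10, d / 4)
        idx <- which(tMs >= ev$onset_ms[i] & tMs <= ev$offset_ms[i])
        u <- tMs[idx]
        shape <- pmin(1, pmin((u - ev$onset_ms[i]) / rise,
                              (ev$offset_ms[i] - u) / rise))
        x[idx] <- x[idx] + pol * config@eogDeflectionUv * pmax(0, shape)
      }
    } else {
      phase <- runif(1, 0, 2 * pi)
      x <- .onePerFNoise(nS, fs, config@noiseUv) +
        config@alphaBaseUv * envA[[ch$roi[j]]] * sin(2 * pi * 10 * tS + phase) +
        envG[[ch$roi[j]]] *
          .bandNoise(nS, fs, 70, 110, config@gammaBaseUv / sqrt(2))
    }
    sig[, j] <- x
  }
  rec <- new("Recording", signals = sig, samplingRate = fs, channels = ch)

  ## ground-truth percent-change curves on the band analysis grids
  curves <- list()
  for (i in seq_len(nrow(mp))) {
    spec <- bandSpec(mp$band[i])
    g <- epochGrid(spec$binMs)
    ct <- g$centers[g$centers >= g$analysis[1] & g$centers <= g$analysis[2]]
    curves[[i]] <- data.frame(
      roi = mp$roi[i], hemisphere = "both", band = mp$band[i],
      mark = paste(mp$kind[i], mp$mark_edge[i], sep = "_"), time_ms = ct,
      pct = mp$peak_pct[i] * .bumpShape(ct, mp$onset_ms[i],
                                        mp$onset_ms[i] + mp$duration_ms[i],
                                        mp$ramp_ms[i]),
      stringsAsFactors = FALSE)
  }
  truth <- new("GroundTruth", schedule = events,
               curves = if (length(curves)) do.call(rbind, curves)
                        else data.frame(),
               streamlineLabels = data.frame())
  list(recording = rec, truth = truth)
}

## smooth major-arc polyline between two points (length > straight distance)
.arcLine <- function(a, b, radius, stepMm = 5) {
  d <- sqrt(sum((b - a)^2))
  mid <- (a + b) / 2
  u <- (b - a) / d
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- ref - sum(ref * u) * u
  perp <- perp / sqrt(sum(perp^2))
  h <- sqrt(radius^2 - (d / 2)^2)
  ctr <- mid + perp * h
  va <- a - ctr; vb <- b - ctr
  e1 <- va / sqrt(sum(va^2))
  w <- vb - sum(vb * e1) * e1
  e2 <- w / sqrt(sum(w^2))
  angB <- atan2(sum(vb * e2), sum(vb * e1))
  ## go the long way round (negative sweep to -(2*pi - angB))
  sweep <- -(2 * pi - angB)
  nPts <- max(8L, ceiling(abs(sweep) * radius / stepMm))
  ang <- seq(0, sweep, length.out = nPts)
  t(vapply(ang, function(th) ctr + radius * (cos(th) * e1 + sin(th) * e2),
           numeric(3)))
}

#' Synthesize labelled streamline fixtures between ROI centroids
#'
#' Emits one valid polyline per ROI pair (gently curved, 10-250 mm, QA 0.10)
#' plus deliberate violators of each legitimacy criterion: too short
#' (< 10 mm), too long (> 250 mm), an 80 degree turning angle, a vertex with
#' quantitative anisotropy below 0.05, and a vertex inside an exclusion-mask
#' box. Labels record each streamline's validity and violated criterion.
#'
#' @param roiGeometry data.frame with columns roi, x_mm, y_mm, z_mm (ROI
#'   centroid coordinates).
#' @param config a \code{\link{SimConfig}} (seed and mask geometry).
#' @return list(streamlines = \code{\link{StreamlineSet}}, labels =
#'   data.frame(id, roi_a, roi_b, valid, violation)).
#' @export
synthesizeStreamlines <- function(roiGeometry, config = simConfig()) {
  if (!is.data.frame(roiGeometry) || nrow(roiGeometry) < 2L)
    stop("roiGeometry must supply at least 2 ROI centroids")
  stopifnot(all(c("roi", "x_mm", "y_mm", "z_mm") %in% names(roiGeometry)))
  set.seed(deriveSeed(config@seed, "streamlines"))
  cent <- as.matrix(roiGeometry[, c("x_mm", "y_mm", "z_mm")])
  rownames(cent) <- roiGeometry$roi
  lo <- apply(cent, 2, min) - 150
  hi <- apply(cent, 2, max) + 150
  excl <- list(min = colMeans(cent) + c(-10, -10, -70),
               max = colMeans(cent) + c(10, 10, -50))
  masks <- list(parenchyma = list(min = lo, max = hi), exclude = list(excl))

  lines <- list(); qa <- list(); ids <- character()
  lab <- list()
  addLine <- function(pts, qav, id, ra, rb, valid, violation) {
    dimnames(pts) <- NULL
    lines[[length(lines) + 1L]] <<- pts
    qa[[length(qa) + 1L]] <<- qav
    ids[length(ids) + 1L] <<- id
    lab[[length(lab) + 1L]] <<- data.frame(
      id = id, roi_a = ra, roi_b = rb, valid = valid, violation = violation,
      stringsAsFactors = FALSE)
  }
  seg <- function(a, b, stepMm = 4) {
    d <- sqrt(sum((b - a)^2))
    n <- max(3L, ceiling(d / stepMm) + 1L)
    t(vapply(seq(0, 1, length.out = n), function(s) a + s * (b - a),
             numeric(3)))
  }

  pairs <- utils::combn(nrow(cent), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- cent[pairs[1, k], ]; b <- cent[pairs[2, k], ]
    d <- sqrt(sum((b - a)^2))
    if (d < 10 || d > 250) next
    pts <- seg(a, b)
    id <- sprintf("sl_valid_%03d", k)
    addLine(pts, rep(0.10, nrow(pts)), id,
            rownames(cent)[pairs[1, k]], rownames(cent)[pairs[2, k]],
            TRUE, "")
  }
  a <- cent[1, ]; b <- cent[2, ]
  ## short: < 10 mm
  addLine(seg(a, a + c(5, 0, 0), stepMm = 2), rep(0.10, 4), "sl_short",
          NA, NA, FALSE, "length")
  ## long: major arc > 250 mm
  arc <- .arcLine(a, b, radius = max(60, sqrt(sum((b - a)^2)) / 2 + 10))
  addLine(arc, rep(0.10, nrow(arc)), "sl_long", NA, NA, FALSE, "length")
  ## sharp bend: 80 degrees between successive segments
  u <- (b - a) / sqrt(sum((b - a)^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- ref - sum(ref * u) * u; perp <- perp / sqrt(sum(perp^2))
  th <- 80 * pi / 180
  bend <- rbind(a, a + 20 * u, a + 20 * u + 20 * (cos(th) * u + sin(th) * perp))
  addLine(bend, rep(0.10, 3), "sl_bend", NA, NA, FALSE, "turning angle")
  ## low QA vertex
  pts <- seg(a, b)
  qav <- rep(0.10, nrow(pts)); qav[ceiling(nrow(pts) / 2)] <- 0.02
  addLine(pts, qav, "sl_lowqa", NA, NA, FALSE, "qa")
  ## straight line passing through the exclusion box
  mid <- (excl$min + excl$max) / 2
  pts <- seg(mid + c(0, 0, 40), mid - c(0, 0, 40))
  addLine(pts, rep(0.10, nrow(pts)), "sl_masked", NA, NA, FALSE,
          "exclusion mask")

  list(streamlines = new("StreamlineSet", lines = lines, qa = qa, ids = ids,
                         masks = masks),
       labels = do.call(rbind, lab))
}
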