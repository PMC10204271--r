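## Complex-demodulation band-amplitude estimation (Gabor-equivalent: complex
## exponential mixing followed by a Gaussian FIR low-pass) and event-locked
## percent-change mapping against the pre-movement baseline.

#' Analysis-band specification
#'
#' The two analysis bands with their time-frequency bin sizes and Gaussian
#' kernel half-power resolutions: alpha 8-12 Hz analysed in 25 ms x 2 Hz bins
#' with +/-39.4 ms temporal resolution, high gamma 70-110 Hz in 5 ms x 10 Hz
#' bins with +/-7.9 ms. Frequency-bin centres are 9/11 Hz (alpha) and
#' 75/85/95/105 Hz (high gamma). The half-power frequency follows from the
#' time value through Gaussian duality (f_h = ln 2 / (2 pi t_h)).
#'
#' @param band \code{"alpha"} or \code{"high_gamma"}.
#' @return list(band, low, high, binHz, binMs, halfPowerMs, halfPowerHz,
#'   freqCenters).
#' @export
bandSpec <- function(band = c("alpha", "high_gamma")) {
  band <- match.arg(band)
  if (band == "alpha")
    list(band = "alpha", low = 8, high = 12, binHz = 2, binMs = 25,
         halfPowerMs = 39.4, halfPowerHz = 2.8, freqCenters = c(9, 11))
  else
    list(band = "high_gamma", low = 70, high = 110, binHz = 10, binMs = 5,
         halfPowerMs = 7.9, halfPowerHz = 14.2,
         freqCenters = c(75, 85, 95, 105))
}

#' Epoch grid around a behavioural mark
#'
#' Bin centres at \code{binMs} steps over the full -1000..+2000 ms window;
#' the analysis window is -200..+2000 ms (inclusive: 89 centres at 25 ms,
#' 441 at 5 ms) and the baseline window is -600..-200 ms relative to the
#' movement onset.
#'
#' @param binMs time-bin width in ms.
#' @return list(centers, binMs, window, analysis, baseline).
#' @export
epochGrid <- function(binMs) {
  stopifnot(binMs > 0)
  list(centers = seq(-1000, 2000, by = binMs), binMs = binMs,
       window = c(-1000, 2000), analysis = c(-200, 2000),
       baseline = c(-600, -200))
}

#' Design the Gaussian low-pass FIR kernel
#'
#' Truncated (+/- 4 sigma) Gaussian with unit DC gain whose time-domain
#' power envelope falls to 50\% at \code{+/- halfPowerMs}; by Gaussian
#' time-frequency duality its transfer-function power falls to 50\% at
#' ln 2 / (2 pi t_h) Hz.
#'
#' @param halfPowerMs time-domain half-power half-width (ms).
#' @param samplingRate Hz.
#' @return numeric kernel (odd length, sums to 1) with attributes
#'   \code{halfPowerMs}, \code{sigmaS} and \code{samplingRate}.
#' @export
designGaussianLowpass <- function(halfPowerMs, samplingRate) {
  stopifnot(halfPowerMs > 0, samplingRate > 0)
  th <- halfPowerMs / 1000
  dt <- 1 / samplingRate
  if (th < 2 * dt)
    stop("halfPowerMs must be at least two sampling intervals")
  sigma <- th / sqrt(log(2))        # g(t)^2 = 0.5 g(0)^2 at t = th
  half <- ceiling(4 * sigma / dt)
  tt <- (-half:half) * dt
  k <- exp(-tt^2 / (2 * sigma^2))
  k <- k / sum(k)
  attr(k, "halfPowerMs") <- halfPowerMs
  attr(k, "sigmaS") <- sigma
  attr(k, "samplingRate") <- samplingRate
  k
}

#' Measure a kernel's frequency half-power point
#'
#' Evaluates the transfer function on a dense FFT grid and interpolates the
#' frequency at which power (|H|^2) first drops to one half.
#'
#' @param kernel FIR kernel (e.g. from \code{\link{designGaussianLowpass}}).
#' @param samplingRate Hz.
#' @return frequency half-power half-width in Hz.
#' @export
measureFreqHalfPower <- function(kernel, samplingRate) {
  N <- max(2^17, nextn(length(kernel), 2))
  H <- fft(c(as.numeric(kernel), rep(0, N - length(kernel))))
  p <- Mod(H[seq_len(N %/% 2)])^2
  p <- p / p[1]
  f <- (seq_len(N %/% 2) - 1) * samplingRate / N
  i <- which(p <= 0.5)[1]
  ## linear interpolation between the straddling grid points
  f[i - 1] + (0.5 - p[i - 1]) * (f[i] - f[i - 1]) / (p[i] - p[i - 1])
}

## same-size FFT convolution, complex-capable (kernel length must be odd)
.fftConvSame <- function(x, k) {
  n <- length(x); m <- length(k)
  if (m > n) stop("kernel longer than signal")
  N <- nextn(n + m - 1, 2)
  y <- fft(fft(c(x, rep(0, N - n))) * fft(c(k, rep(0, N - m))),
           inverse = TRUE) / N
  y[((m - 1) %/% 2 + 1):((m - 1) %/% 2 + n)]
}

#' Complex demodulation at a centre frequency
#'
#' Multiplies the signal by a complex exponential at \code{f0} and low-passes
#' with the supplied Gaussian kernel; the amplitude is scaled so a pure
#' sinusoid of peak amplitude A at \code{f0} returns A in steady state.
#' Samples within one kernel half-length of either edge are unreliable; the
#' returned vector carries their count as attribute \code{edgeSamples}.
#'
#' @param x voltage series (microvolts).
#' @param samplingRate Hz.
#' @param f0 centre frequency (Hz), below Nyquist.
#' @param kernel low-pass kernel from \code{\link{designGaussianLowpass}}.
#' @return amplitude series (same length as \code{x}).
#' @export
demodulate <- function(x, samplingRate, f0, kernel) {
  stopifnot(f0 > 0, f0 < samplingRate / 2)
  if (length(kernel) > length(x)) stop("kernel longer than signal")
  tS <- (seq_along(x) - 1) / samplingRate
  z <- x * exp(-2i * pi * f0 * tS)
  amp <- 2 * Mod(.fftConvSame(z, as.numeric(kernel)))
  attr(amp, "edgeSamples") <- (length(kernel) - 1) %/% 2
  amp
}

#' Band amplitude for every iEEG channel
#'
#' Demodulates each non-EOG channel at the band's frequency-bin centres and
#' averages the per-centre amplitudes, giving one band-amplitude series per
#' site.
#'
#' @param recording a \code{\link{Recording}}.
#' @param band \code{"alpha"} or \code{"high_gamma"}.
#' @param spec band specification, defaults to \code{\link{bandSpec}(band)}.
#' @return numeric matrix samples x sites (colnames are site ids).
#' @export
bandAmplitude <- function(recording, band = c("alpha", "high_gamma"),
                          spec = bandSpec(band)) {
  band <- match.arg(band)
  fs <- samplingRate(recording)
  kernel <- designGaussianLowpass(spec$halfPowerMs, fs)
  ch <- channelTable(recording)
  idx <- which(ch$type == "ieeg")
  sig <- signalMatrix(recording)
  amp <- matrix(0, nrow(sig), length(idx))
  colnames(amp) <- ch$site_id[idx]
  for (j in seq_along(idx)) {
    a <- 0
    for (f0 in spec$freqCenters)
      a <- a + demodulate(sig[, idx[j]], fs, f0, kernel)
    amp[, j] <- a / length(spec$freqCenters)
  }
  amp
}

## windowed mean over [center - binMs/2, center + binMs/2] via cumulative sums
.binMeans <- function(cumAmp, startIdx, endIdx) {
  (cumAmp[endIdx + 1L] - cumAmp[startIdx]) / (endIdx - startIdx + 1L)
}

#' Event-locked percent-change map
#'
#' Epochs each site's band amplitude around the chosen behavioural mark on
#' the band's bin-centre grid, averages across events (trial-average), and
#' expresses each bin as percent change versus the baseline 200-600 ms
#' before the movement onset. The baseline is always anchored to the event
#' onset, also when epochs are aligned to an offset mark. For onset-aligned
#' maps the baseline-bin mean of the map is zero by construction.
#'
#' @param recording a \code{\link{Recording}}.
#' @param events an \code{\link{EyeEventSet}}.
#' @param band \code{"alpha"} or \code{"high_gamma"}.
#' @param mark one of \code{"closure_onset"}, \code{"closure_offset"},
#'   \code{"opening_onset"}, \code{"opening_offset"}.
#' @param amplitude optional precomputed matrix from
#'   \code{\link{bandAmplitude}} (avoids re-demodulating when several marks
#'   are mapped from one recording).
#' @param spec band specification.
#' @return A \code{\link{PercentChangeMap}}.
#' @export
percentChangeMap <- function(recording, events, band = c("alpha", "high_gamma"),
                             mark = MARKS, amplitude = NULL,
                             spec = bandSpec(band)) {
  band <- match.arg(band)
  mark <- match.arg(mark)
  fs <- samplingRate(recording)
  grid <- epochGrid(spec$binMs)
  if (is.null(amplitude))
    amplitude <- bandAmplitude(recording, band, spec)
  ev <- eventTable(events)
  kind <- sub("_(onset|offset)$", "", mark)
  edge <- sub("^.*_", "", mark)
  ev <- ev[ev$kind == kind, , drop = FALSE]
  if (!nrow(ev)) stop("no ", kind, " events to epoch")
  markT <- if (edge == "onset") ev$onset_ms else ev$offset_ms
  anchorT <- ev$onset_ms                      # baseline anchor: movement onset
  nS <- nrow(amplitude)
  halfBin <- spec$binMs / 2

  toIdx <- function(ms) as.integer(round(ms / 1000 * fs)) + 1L
  ## keep events whose epoch and baseline windows lie inside the recording
  lo <- pmin(markT + grid$window[1] - halfBin, anchorT + grid$baseline[1])
  hi <- pmax(markT + grid$window[2] + halfBin, anchorT + grid$baseline[2])
  keep <- toIdx(lo) >= 1L & toIdx(hi) <= nS
  dropped <- sum(!keep)
  if (dropped)
    message(sprintf("percentChangeMap: dropped %d %s event(s) outside the recording",
                    dropped, kind))
  markT <- markT[keep]; anchorT <- anchorT[keep]
  if (!length(markT)) stop("all events fall outside the recording")

  centers <- grid$centers
  nBins <- length(centers)
  pct <- matrix(0, ncol(amplitude), nBins,
                dimnames = list(colnames(amplitude), NULL))
  baseIdx <- which(centers >= grid$baseline[1] & centers <= grid$baseline[2])
  for (s in seq_len(ncol(amplitude))) {
    cumAmp <- c(0, cumsum(amplitude[, s]))
    binSum <- numeric(nBins)
    baseSum <- 0
    for (e in seq_along(markT)) {
      st <- toIdx(markT[e] + centers - halfBin)
      en <- toIdx(markT[e] + centers + halfBin) - 1L
      binSum <- binSum + .binMeans(cumAmp, st, en)
      bs <- toIdx(anchorT[e] + grid$baseline[1])
      be <- toIdx(anchorT[e] + grid$baseline[2]) - 1L
      baseSum <- baseSum + (cumAmp[be + 1L] - cumAmp[bs]) / (be - bs + 1L)
    }
    aBar <- binSum / length(markT)
    aBase <- if (edge == "onset") mean(aBar[baseIdx])
             else baseSum / length(markT)
    if (!is.finite(aBase) || aBase == 0)
      stop("zero baseline amplitude; cannot form percent change")
    pct[s, ] <- 100 * (aBar - aBase) / aBase
  }
  new("PercentChangeMap", pct = pct, band = band, mark = mark,
      timeMs = centers, baselineMs = grid$baseline,
      analysisMs = grid$analysis, nTrials = length(markT),
      droppedEvents = as.integer(dropped))
}
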