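## EOG processing: first-order high-pass matching the clinical amplifier
## time constant, and automated threshold-based eye-event detection.

#' First-order high-pass filter with a given time constant
#'
#' Discrete RC high-pass with \code{RC = timeConstantS} (cut-off
#' 1/(2 pi RC) Hz), the digital equivalent of an EEG amplifier "time
#' constant" setting: a step of height V decays to V/e after RC seconds.
#'
#' @param x EOG voltage series (microvolts).
#' @param samplingRate Hz.
#' @param timeConstantS RC time constant in seconds (default 1.0).
#' @return filtered series, same length.
#' @export
highpassTimeConstant <- function(x, samplingRate, timeConstantS = 1.0) {
  stopifnot(samplingRate > 0, timeConstantS > 0)
  if (anyNA(x) || any(!is.finite(x))) stop("input must be finite")
  n <- length(x)
  if (!n) return(numeric(0))
  a <- timeConstantS / (timeConstantS + 1 / samplingRate)
  y <- numeric(n)
  y[1] <- x[1]
  for (i in 2:n) y[i] <- a * (y[i - 1] + x[i] - x[i - 1])
  y
}

## supra-threshold deflections of one polarity, with half-threshold
## hysteresis on the return: onset = first crossing above `threshold`,
## offset = first return below `hysteresis`.
.deflections <- function(v, fs, threshold, hysteresis) {
  above <- v > threshold
  out <- list()
  i <- 1L; n <- length(v)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && v[j + 1L] > hysteresis) j <- j + 1L
      out[[length(out) + 1L]] <- c(onset = (i - 1L) / fs * 1000,
                                   offset = j / fs * 1000)
      i <- j + 1L
    }
    i <- i + 1L
  }
  out
}

#' Detect eye-closure and eye-opening events from an EOG trace
#'
#' A closure event is a supra-threshold deflection of closure polarity
#' (positive by default): onset at the first sample above \code{thresholdUv},
#' offset at the return below half the threshold (hysteresis, since the
#' marking rule defines only the 50 microvolt crossing). Openings are the
#' opposite polarity. Any closure whose onset lies within
#' \code{separationS} of an opening onset is removed, and vice versa. The
#' result is flagged insufficient (not an error) when either kind has fewer
#' than \code{minPerKind} events.
#'
#' @param x high-pass-filtered EOG series (microvolts); see
#'   \code{\link{highpassTimeConstant}}.
#' @param samplingRate Hz.
#' @param thresholdUv deflection threshold (default 50).
#' @param separationS opposite-kind exclusion window in seconds (default 2).
#' @param minPerKind minimum events per kind before flagging (default 16).
#' @param closurePolarity +1 if closure deflects positive (default), -1
#'   otherwise.
#' @return An \code{\link{EyeEventSet}}.
#' @export
detectEvents <- function(x, samplingRate, thresholdUv = 50, separationS = 2,
                         minPerKind = 16, closurePolarity = 1) {
  if (thresholdUv <= 0) stop("thresholdUv must be positive")
  stopifnot(closurePolarity %in% c(-1, 1))
  hyst <- thresholdUv / 2
  clo <- .deflections(closurePolarity * x, samplingRate, thresholdUv, hyst)
  opn <- .deflections(-closurePolarity * x, samplingRate, thresholdUv, hyst)
  mk <- function(lst, kind)
    if (length(lst)) data.frame(kind = kind,
                                onset_ms = vapply(lst, `[[`, 0, "onset"),
                                offset_ms = vapply(lst, `[[`, 0, "offset"),
                                stringsAsFactors = FALSE)
    else data.frame(kind = character(), onset_ms = numeric(),
                    offset_ms = numeric())
  ev <- rbind(mk(clo, "closure"), mk(opn, "opening"))
  ev <- ev[order(ev$onset_ms), , drop = FALSE]
  ## opposite-kind proximity rule (applied symmetrically, so it is idempotent)
  if (nrow(ev)) {
    sepMs <- separationS * 1000
    cOn <- ev$onset_ms[ev$kind == "closure"]
    oOn <- ev$onset_ms[ev$kind == "opening"]
    near <- function(t, other)
      length(other) > 0 && any(abs(other - t) <= sepMs)
    drop <- logical(nrow(ev))
    for (i in seq_len(nrow(ev)))
      drop[i] <- near(ev$onset_ms[i],
                      if (ev$kind[i] == "closure") oOn else cOn)
    ev <- ev[!drop, , drop = FALSE]
  }
  rownames(ev) <- NULL
  counts <- c(sum(ev$kind == "closure"), sum(ev$kind == "opening"))
  new("EyeEventSet", events = ev, insufficient = any(counts < minPerKind),
      minPerKind = minPerKind)
}

#' Extract the EOG channel from a recording
#'
#' @param recording a \code{\link{Recording}}.
#' @return numeric vector (microvolts) of the first EOG-typed channel.
#' @export
eogTrace <- function(recording) {
  ch <- channelTable(recording)
  i <- which(ch$type == "eog")
  if (!length(i)) stop("recording has no EOG channel")
  signalMatrix(recording)[, i[1]]
}
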