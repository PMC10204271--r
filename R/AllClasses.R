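## S4 containers for the pipeline. All voltages are in microvolts, times in
## milliseconds unless a name says otherwise, distances in millimetres.

REQUIRED_CHANNEL_COLS <- c("site_id", "patient_id", "roi", "hemisphere",
                           "type", "excluded", "exclusion_reason",
                           "x_mm", "y_mm", "z_mm")

#' Multichannel voltage recording (iEEG + EOG)
#'
#' Samples are stored as a numeric matrix with one column per channel and one
#' row per sample; \code{channels} carries one metadata row per column
#' (site id, patient, ROI label, hemisphere, channel type \code{"ieeg"} or
#' \code{"eog"}, exclusion flag with reason, and 3-D coordinates plus optional
#' flat-map coordinates \code{flat_x_mm}/\code{flat_y_mm}).
#'
#' @slot signals numeric matrix, samples x channels, microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channels data.frame of per-channel metadata.
#' @export
setClass("Recording",
  slots = c(signals = "matrix", samplingRate = "numeric",
            channels = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (!all(REQUIRED_CHANNEL_COLS %in% names(object@channels)))
      msg <- c(msg, paste("channels must have columns:",
                          paste(REQUIRED_CHANNEL_COLS, collapse = ", ")))
    if (ncol(object@signals) != nrow(object@channels))
      msg <- c(msg, "one channel metadata row per signal column is required")
    if (anyNA(object@signals) || any(!is.finite(object@signals)))
      msg <- c(msg, "signals must be finite")
    if (length(msg)) msg else TRUE
  })

#' Timed eye-closure and eye-opening events
#'
#' @slot events data.frame with columns \code{kind} (\code{"closure"} or
#'   \code{"opening"}), \code{onset_ms}, \code{offset_ms}; time-ordered and
#'   non-overlapping.
#' @slot insufficient TRUE when either kind has fewer events than the
#'   configured minimum (a cohort-inclusion style flag, not an error).
#' @slot minPerKind the minimum count used to set \code{insufficient}.
#' @export
setClass("EyeEventSet",
  slots = c(events = "data.frame", insufficient = "logical",
            minPerKind = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    if (!all(c("kind", "onset_ms", "offset_ms") %in% names(ev)))
      msg <- c(msg, "events needs columns kind, onset_ms, offset_ms")
    else if (nrow(ev)) {
      if (!all(ev$kind %in% c("closure", "opening")))
        msg <- c(msg, "kind must be 'closure' or 'opening'")
      if (any(ev$offset_ms <= ev$onset_ms))
        msg <- c(msg, "every offset must exceed its onset")
      if (is.unsorted(ev$onset_ms))
        msg <- c(msg, "events must be ordered by onset")
      if (nrow(ev) > 1L && any(ev$onset_ms[-1L] < ev$offset_ms[-nrow(ev)]))
        msg <- c(msg, "events must not overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' Event-locked percent-change map for one band and one behavioural mark
#'
#' Per-site amplitude percent change versus the pre-movement baseline
#' (200-600 ms before eye-movement onset), on the bin-centre grid of the band
#' (25 ms for alpha, 5 ms for high gamma) spanning the full -1000..+2000 ms
#' window around the mark.
#'
#' @slot pct numeric matrix, sites x time bins, percent.
#' @slot band \code{"alpha"} or \code{"high_gamma"}.
#' @slot mark one of \code{"closure_onset"}, \code{"closure_offset"},
#'   \code{"opening_onset"}, \code{"opening_offset"}.
#' @slot timeMs bin-centre times relative to the mark.
#' @slot baselineMs baseline window (relative to movement onset).
#' @slot analysisMs analysis window.
#' @slot nTrials number of events averaged.
#' @slot droppedEvents events dropped because their window left the recording.
#' @export
setClass("PercentChangeMap",
  slots = c(pct = "matrix", band = "character", mark = "character",
            timeMs = "numeric", baselineMs = "numeric",
            analysisMs = "numeric", nTrials = "integer",
            droppedEvents = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@pct) != length(object@timeMs))
      msg <- c(msg, "one time stamp per pct column is required")
    if (!object@band %in% c("alpha", "high_gamma"))
      msg <- c(msg, "band must be 'alpha' or 'high_gamma'")
    if (!object@mark %in% MARKS)
      msg <- c(msg, paste("mark must be one of:", paste(MARKS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

MARKS <- c("closure_onset", "closure_offset", "opening_onset", "opening_offset")

#' Per-ROI bootstrap series with significance masks
#'
#' Long-format studentized-bootstrap summary per (ROI, hemisphere, band, mark,
#' time bin): mean percent change, lower/upper CI bounds, and augmentation /
#' attenuation masks from the run-length rule; plus per-ROI onset latencies.
#'
#' @slot table data.frame (roi, hemisphere, band, mark, time_ms, mean, lo, hi,
#'   sig_aug, sig_att, n_sites).
#' @slot onsets data.frame (roi, hemisphere, band, mark, onset_aug_ms,
#'   onset_att_ms, peak_pct).
#' @slot level CI level.
#' @slot minRun minimum consecutive significant bins.
#' @slot nResamples bootstrap resamples.
#' @export
setClass("ROISeries",
  slots = c(table = "data.frame", onsets = "data.frame", level = "numeric",
            minRun = "integer", nResamples = "integer"),
  validity = function(object) {
    tb <- object@table
    need <- c("roi", "hemisphere", "band", "mark", "time_ms",
              "mean", "lo", "hi", "sig_aug", "sig_att")
    if (!all(need %in% names(tb)))
      return(paste("table needs columns:", paste(need, collapse = ", ")))
    if (nrow(tb) && any(tb$lo > tb$mean + 1e-9 | tb$hi < tb$mean - 1e-9))
      return("CI bounds must bracket the mean")
    TRUE
  })

#' White-matter streamline set
#'
#' Polylines of ordered 3-D vertices (mm) with per-vertex quantitative
#' anisotropy, plus optional axis-aligned box masks: \code{parenchyma} (every
#' vertex must lie inside) and \code{exclude} (a list of boxes no vertex may
#' enter; brainstem, basal ganglia, thalamus). A box is
#' \code{list(min = c(x, y, z), max = c(x, y, z))}.
#'
#' @slot lines list of n x 3 vertex matrices.
#' @slot qa list of per-vertex quantitative-anisotropy vectors.
#' @slot ids streamline identifiers.
#' @slot masks list with optional elements \code{parenchyma} and \code{exclude}.
#' @export
setClass("StreamlineSet",
  slots = c(lines = "list", qa = "list", ids = "character", masks = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@lines) != length(object@qa) ||
        length(object@lines) != length(object@ids))
      msg <- c(msg, "lines, qa and ids must have equal length")
    bad <- vapply(object@lines,
                  function(m) !is.matrix(m) || ncol(m) != 3L || nrow(m) < 2L,
                  logical(1))
    if (any(bad))
      msg <- c(msg, "every polyline must be a matrix with >= 2 rows and 3 columns")
    nv <- vapply(object@lines, nrow, integer(1))
    nq <- vapply(object@qa, length, integer(1))
    if (length(nv) && any(nv != nq))
      msg <- c(msg, "one QA value per vertex is required")
    if (length(msg)) msg else TRUE
  })

#' Time-resolved strengthened/weakened connectivity edges
#'
#' @slot edges data.frame (roi_a, roi_b, band, polarity, t_start_ms, t_end_ms,
#'   n_streamlines); polarity is \code{"strengthened"} (co-augmentation) or
#'   \code{"weakened"} (co-attenuation).
#' @slot droppedNoAdjacency co-modulation epochs discarded because their ROI
#'   pair had no legitimate streamline.
#' @export
setClass("DynamicEdgeTable",
  slots = c(edges = "data.frame", droppedNoAdjacency = "integer"),
  validity = function(object) {
    need <- c("roi_a", "roi_b", "band", "polarity",
              "t_start_ms", "t_end_ms", "n_streamlines")
    if (!all(need %in% names(object@edges)))
      return(paste("edges needs columns:", paste(need, collapse = ", ")))
    if (nrow(object@edges)) {
      if (!all(object@edges$polarity %in% c("strengthened", "weakened")))
        return("polarity must be 'strengthened' or 'weakened'")
      if (any(object@edges$n_streamlines < 1L))
        return("every edge needs at least one supporting streamline")
    }
    TRUE
  })

#' Simulation configuration for the synthetic-data generator
#'
#' Defaults reproduce the study conditions the generator emulates: 1000 Hz
#' sampling, log-normal event durations with median 176 ms (closure) / 175 ms
#' (opening) matched to the printed inter-quartile ranges, opposite-kind
#' events separated by more than 2 s, and EOG deflections of 100 microvolts
#' (the detection rule requires > 50).
#'
#' @slot samplingRate Hz.
#' @slot nEventsPerKind events per kind to schedule.
#' @slot closureDurMedianMs,openingDurMedianMs median movement durations.
#' @slot closureDurIqrMs,openingDurIqrMs duration inter-quartile ranges.
#' @slot interEventGapS length-2 range (s) of the gap between one event's
#'   offset and the next event's onset; the minimum must exceed 2 s.
#' @slot channelTable electrode/EOG metadata (see \code{\link{Recording}}).
#' @slot modulationProfiles data.frame (roi, band, kind, mark_edge, onset_ms,
#'   duration_ms, peak_pct, ramp_ms) of injected envelope modulations; the
#'   modulation starts at \code{onset_ms}, rises as a raised cosine over
#'   \code{ramp_ms}, and returns to zero at \code{onset_ms + duration_ms}.
#' @slot noiseUv 1/f background standard deviation.
#' @slot alphaBaseUv,gammaBaseUv baseline band-component amplitudes.
#' @slot eogDeflectionUv EOG deflection amplitude (> 50 required).
#' @slot eogNoiseUv EOG baseline noise standard deviation.
#' @slot durationS recording duration; NA lets the schedule decide.
#' @slot seed integer seed fanned out to per-stage derived seeds.
#' @export
setClass("SimConfig",
  slots = c(samplingRate = "numeric", nEventsPerKind = "numeric",
            closureDurMedianMs = "numeric", openingDurMedianMs = "numeric",
            closureDurIqrMs = "numeric", openingDurIqrMs = "numeric",
            interEventGapS = "numeric", channelTable = "data.frame",
            modulationProfiles = "data.frame", noiseUv = "numeric",
            alphaBaseUv = "numeric", gammaBaseUv = "numeric",
            eogDeflectionUv = "numeric", eogNoiseUv = "numeric",
            durationS = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be positive")
    if (object@nEventsPerKind < 0)
      msg <- c(msg, "nEventsPerKind must be >= 0")
    if (object@eogDeflectionUv <= 50)
      msg <- c(msg, "eogDeflectionUv must exceed the 50 microvolt detection threshold")
    if (length(object@interEventGapS) != 2L ||
        object@interEventGapS[1] <= 2 ||
        diff(object@interEventGapS) < 0)
      msg <- c(msg, "interEventGapS must be an increasing range with minimum > 2 s")
    mp <- object@modulationProfiles
    if (nrow(mp)) {
      if (!all(mp$band %in% c("alpha", "high_gamma")))
        msg <- c(msg, "profile band must be 'alpha' or 'high_gamma'")
      if (!all(mp$kind %in% c("closure", "opening")))
        msg <- c(msg, "profile kind must be 'closure' or 'opening'")
      if (!all(mp$mark_edge %in% c("onset", "offset")))
        msg <- c(msg, "profile mark_edge must be 'onset' or 'offset'")
      if (any(mp$onset_ms < -200))
        msg <- c(msg, "profiles must not reach into the baseline window (before -200 ms)")
      known <- unique(object@channelTable$roi[object@channelTable$type == "ieeg"])
      if (!all(mp$roi %in% known))
        msg <- c(msg, "every profile ROI must appear in channelTable")
    }
    if (length(msg)) msg else TRUE
  })

#' Ground truth for generator output
#'
#' @slot schedule the scheduled \code{\link{EyeEventSet}}.
#' @slot curves data.frame (roi, hemisphere, band, mark, time_ms, pct) of
#'   injected percent-change curves on the analysis grid; exactly zero over
#'   the baseline window.
#' @slot streamlineLabels data.frame (id, roi_a, roi_b, valid, violation).
#' @export
setClass("GroundTruth",
  slots = c(schedule = "EyeEventSet", curves = "data.frame",
            streamlineLabels = "data.frame"))
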