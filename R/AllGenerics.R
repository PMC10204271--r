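#' Accessors for pipeline containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{signalMatrix}/\code{samplingRate}/\code{channelTable} for
#' \code{\link{Recording}}, \code{eventTable}/\code{eventCounts} for
#' \code{\link{EyeEventSet}}, \code{pctValues}/\code{binTimes} for
#' \code{\link{PercentChangeMap}}, \code{seriesTable}/\code{onsetTable} for
#' \code{\link{ROISeries}}, \code{streamlineCount} for
#' \code{\link{StreamlineSet}} and \code{edgeTable} for
#' \code{\link{DynamicEdgeTable}}.
#'
#' @param x an object of the matching class.
#' @return The underlying matrix, data.frame or scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))
#' @rdname accessors
#' @export
setGeneric("pctValues", function(x) standardGeneric("pctValues"))
#' @rdname accessors
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesTable", function(x) standardGeneric("seriesTable"))
#' @rdname accessors
#' @export
setGeneric("onsetTable", function(x) standardGeneric("onsetTable"))
#' @rdname accessors
#' @export
setGeneric("streamlineCount", function(x) standardGeneric("streamlineCount"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setMethod("signalMatrix", "Recording", function(x) x@signals)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelTable", "Recording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("eventTable", "EyeEventSet", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("eventCounts", "EyeEventSet", function(x) {
  c(closure = sum(x@events$kind == "closure"),
    opening = sum(x@events$kind == "opening"))
})
#' @rdname accessors
#' @export
setMethod("pctValues", "PercentChangeMap", function(x) x@pct)
#' @rdname accessors
#' @export
setMethod("binTimes", "PercentChangeMap", function(x) x@timeMs)
#' @rdname accessors
#' @export
setMethod("seriesTable", "ROISeries", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("onsetTable", "ROISeries", function(x) x@onsets)
#' @rdname accessors
#' @export
setMethod("streamlineCount", "StreamlineSet", function(x) length(x@lines))
#' @rdname accessors
#' @export
setMethod("edgeTable", "DynamicEdgeTable", function(x) x@edges)

setMethod("show", "Recording", function(object) {
  ch <- object@channels
  cat(sprintf("Recording: %d channels (%d iEEG, %d EOG), %d samples @ %g Hz (%.1f s)\n",
              ncol(object@signals), sum(ch$type == "ieeg"), sum(ch$type == "eog"),
              nrow(object@signals), object@samplingRate,
              nrow(object@signals) / object@samplingRate))
  cat(sprintf("  ROIs: %s\n",
              paste(sort(unique(ch$roi[ch$type == "ieeg"])), collapse = ", ")))
})

setMethod("show", "EyeEventSet", function(object) {
  n <- eventCounts(object)
  cat(sprintf("EyeEventSet: %d closure, %d opening events%s\n",
              n["closure"], n["opening"],
              if (object@insufficient) " [flagged insufficient]" else ""))
  if (nrow(object@events))
    cat(sprintf("  span %.1f-%.1f s; median closure duration %.0f ms\n",
                min(object@events$onset_ms) / 1000,
                max(object@events$offset_ms) / 1000,
                median(object@events$offset_ms[object@events$kind == "closure"] -
                       object@events$onset_ms[object@events$kind == "closure"])))
})

setMethod("show", "PercentChangeMap", function(object) {
  cat(sprintf("PercentChangeMap: %s band, mark %s, %d sites x %d bins (%g..%g ms), %d trials\n",
              object@band, object@mark, nrow(object@pct), ncol(object@pct),
              min(object@timeMs), max(object@timeMs), object@nTrials))
})

setMethod("show", "ROISeries", function(object) {
  key <- unique(object@table[, c("roi", "hemisphere", "band", "mark")])
  cat(sprintf("ROISeries: %d ROI series at %.2f%% CI (%d resamples), run >= %d bins\n",
              nrow(key), 100 * object@level, object@nResamples, object@minRun))
  sig <- object@onsets[!is.na(object@onsets$onset_aug_ms) |
                       !is.na(object@onsets$onset_att_ms), , drop = FALSE]
  cat(sprintf("  %d ROI series with significant runs\n", nrow(sig)))
})

setMethod("show", "StreamlineSet", function(object) {
  cat(sprintf("StreamlineSet: %d streamlines, %s masks\n", length(object@lines),
              if (length(object@masks)) paste(names(object@masks), collapse = "+")
              else "no"))
})

setMethod("show", "DynamicEdgeTable", function(object) {
  cat(sprintf("DynamicEdgeTable: %d edges (%d strengthened, %d weakened), %d epochs dropped for lack of streamlines\n",
              nrow(object@edges),
              sum(object@edges$polarity == "strengthened"),
              sum(object@edges$polarity == "weakened"),
              object@droppedNoAdjacency))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %g Hz, %d events/kind, %d channels, %d modulation profiles, seed %d\n",
              object@samplingRate, object@nEventsPerKind,
              nrow(object@channelTable), nrow(object@modulationProfiles),
              as.integer(object@seed)))
})
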