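## End-to-end orchestration: simulate (or load) inputs, detect events, map
## percent change for every mark and band, run ROI statistics, coupling and
## streamline-gated connectivity, and write the atlas bundle.

#' Pipeline configuration
#'
#' Either real inputs (paths to an electrode TSV, a percent-change-ready
#' recording is out of scope for file input here) or the simulate flag with
#' a \code{\link{SimConfig}} — never neither.
#'
#' @param simulate generate inputs with the synthetic-data module.
#' @param sim a \code{\link{SimConfig}} (when \code{simulate}).
#' @param recording optional \code{\link{Recording}} supplied directly.
#' @param streamlines optional \code{\link{StreamlineSet}}.
#' @param bands bands to analyse.
#' @param marks behavioural marks to analyse.
#' @param level CI level (default 0.9999).
#' @param nResamples bootstrap resamples (default 10000).
#' @param minRun minimum consecutive significant bins (default 8).
#' @param minSites minimum sites per ROI (default 4).
#' @param captureRadiusMm streamline endpoint capture radius.
#' @param seed master seed fanned out to per-stage seeds.
#' @param outDir output directory; NULL keeps results in memory only.
#' @return validated config list (class "dyntractConfig").
#' @export
pipelineConfig <- function(simulate = TRUE, sim = simConfig(),
                           recording = NULL, streamlines = NULL,
                           bands = c("alpha", "high_gamma"), marks = MARKS,
                           level = 0.9999, nResamples = 10000, minRun = 8,
                           minSites = 4, captureRadiusMm = 3, seed = 1,
                           outDir = NULL) {
  if (!simulate && is.null(recording))
    stop("invalid config: either 'simulate' must be TRUE or 'recording' must be supplied")
  stopifnot(level > 0, level < 1, nResamples >= 1, minRun >= 1,
            minSites >= 1, captureRadiusMm > 0)
  bands <- match.arg(bands, c("alpha", "high_gamma"), several.ok = TRUE)
  marks <- match.arg(marks, MARKS, several.ok = TRUE)
  structure(list(simulate = simulate, sim = sim, recording = recording,
                 streamlines = streamlines, bands = bands, marks = marks,
                 level = level, nResamples = nResamples, minRun = minRun,
                 minSites = minSites, captureRadiusMm = captureRadiusMm,
                 seed = seed, outDir = outDir),
            class = "dyntractConfig")
}

#' ROI centroid geometry from a channel table
#'
#' @param channels channel metadata data.frame.
#' @return data.frame(roi, x_mm, y_mm, z_mm) with one row per
#'   (hemisphere, ROI), ROI keys formatted "hemisphere roi".
#' @export
roiGeometryFromChannels <- function(channels) {
  el <- channels[channels$type == "ieeg" & !channels$excluded, , drop = FALSE]
  key <- paste(el$hemisphere, el$roi)
  agg <- aggregate(el[, c("x_mm", "y_mm", "z_mm")], by = list(roi = key),
                   FUN = mean)
  agg
}

#' Run the full analysis pipeline
#'
#' Executes event detection, spectral percent-change mapping, ROI bootstrap
#' statistics, alpha/high-gamma coupling and streamline-gated connectivity
#' for the configured marks and bands, optionally writing the atlas bundle
#' (ROI series CSV, coupling CSV, edge CSV/JSON, event TSV, electrode TSV
#' and a manifest JSON) to \code{outDir}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) list with elements \code{recording}, \code{truth},
#'   \code{events}, \code{pct}, \code{roiSeries} and \code{shells} (per
#'   band/mark), \code{coupling}, \code{edges} (per band/mark),
#'   \code{chance} (observed chi and Type I error per band/mark),
#'   \code{adjacency}, \code{filterReport}, \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "dyntractConfig"))
  ## --- inputs -----------------------------------------------------------
  if (config$simulate) {
    sim <- config$sim
    sim@seed <- config$seed
    schedule <- scheduleEvents(sim)
    synth <- synthesizeRecording(sim, schedule)
    recording <- synth$recording
    truth <- synth$truth
  } else {
    recording <- config$recording
    truth <- NULL
  }
  channels <- channelTable(recording)
  roiGeom <- roiGeometryFromChannels(channels)
  if (is.null(config$streamlines)) {
    simForStreams <- if (config$simulate) config$sim else simConfig()
    simForStreams@seed <- config$seed
    sl <- synthesizeStreamlines(roiGeom, simForStreams)
    streamlines <- sl$streamlines
    if (!is.null(truth)) truth@streamlineLabels <- sl$labels
  } else streamlines <- config$streamlines

  ## --- EOG events -------------------------------------------------------
  eog <- highpassTimeConstant(eogTrace(recording), samplingRate(recording))
  events <- detectEvents(eog, samplingRate(recording))
  if (!nrow(eventTable(events))) stop("eog_events: empty event set")

  ## --- spectral + ROI stats + coupling ---------------------------------
  roiSeries <- list(); pcms <- list()
  for (band in config$bands) {
    amp <- bandAmplitude(recording, band)
    for (mark in config$marks) {
      key <- paste(band, mark, sep = ".")
      pcm <- percentChangeMap(recording, events, band, mark, amplitude = amp)
      pcms[[key]] <- pcm
      roiSeries[[key]] <- computeRoiSeries(
        pcm, channels, level = config$level,
        nResamples = config$nResamples, minRun = config$minRun,
        minSites = config$minSites,
        seed = deriveSeed(config$seed, key))
    }
  }
  ## distance-from-calcarine shell profile (flat-map coordinates required)
  shells <- list()
  hasFlat <- any(is.finite(channels$flat_y_mm[channels$type == "ieeg"]))
  if (hasFlat) {
    for (key in names(pcms))
      shells[[key]] <- distanceShellProfile(
        pcms[[key]], channels, level = config$level,
        nResamples = config$nResamples, minRun = config$minRun,
        seed = deriveSeed(config$seed, paste0("shell", key)))
  }

  coupling <- list()
  if (all(c("alpha", "high_gamma") %in% config$bands)) {
    for (mark in config$marks)
      coupling[[mark]] <- couplingTable(
        roiSeries[[paste("alpha", mark, sep = ".")]],
        roiSeries[[paste("high_gamma", mark, sep = ".")]])
  }

  ## --- connectivity -----------------------------------------------------
  filt <- filterStreamlines(streamlines)
  adjacency <- pairAdjacency(filt$streamlines, roiGeom,
                             config$captureRadiusMm)
  edges <- list(); chance <- list()
  for (key in names(roiSeries)) {
    band <- sub("\\..*$", "", key)
    masks <- significanceMasks(roiSeries[[key]])
    epochs <- findComodulation(masks, minRun = config$minRun)
    edges[[key]] <- buildDynamicEdges(epochs, adjacency, band = band)
    chance[[key]] <- data.frame(
      band = band, mark = sub("^[^.]*\\.", "", key),
      chi_aug = observedChi(masks, 1L), chi_att = observedChi(masks, -1L),
      type1_aug = chanceProbability(nRois = nrow(masks),
                                    nBins = ncol(masks),
                                    minRun = config$minRun,
                                    chi = observedChi(masks, 1L)),
      type1_att = chanceProbability(nRois = nrow(masks),
                                    nBins = ncol(masks),
                                    minRun = config$minRun,
                                    chi = observedChi(masks, -1L)),
      stringsAsFactors = FALSE)
  }

  manifest <- list(
    package = "dyntract",
    version = as.character(packageVersion("dyntract")),
    seed = config$seed, level = config$level,
    nResamples = config$nResamples, minRun = config$minRun,
    bands = config$bands, marks = config$marks,
    n_channels = ncol(signalMatrix(recording)),
    n_events = unclass(eventCounts(events)),
    n_events_insufficient = events@insufficient,
    n_streamlines_total = streamlineCount(streamlines),
    n_streamlines_legit = streamlineCount(filt$streamlines),
    n_adjacent_pairs = nrow(adjacency),
    n_edges = vapply(edges, function(e) nrow(edgeTable(e)), integer(1)))

  bundle <- list(recording = recording, truth = truth, events = events,
                 pct = pcms, roiSeries = roiSeries, shells = shells,
                 coupling = coupling, edges = edges, chance = chance,
                 adjacency = adjacency, filterReport = filt$report,
                 manifest = manifest)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeEventSet(events, file.path(config$outDir, "events.tsv"))
    writeElectrodeTable(channels, file.path(config$outDir, "electrodes.tsv"))
    for (key in names(roiSeries))
      writeRoiSeries(roiSeries[[key]],
                     file.path(config$outDir,
                               sprintf("roi_series_%s.csv", key)))
    for (key in names(shells))
      utils::write.csv(shells[[key]],
                       file.path(config$outDir,
                                 sprintf("shell_profile_%s.csv", key)),
                       row.names = FALSE, quote = FALSE)
    for (mark in names(coupling))
      utils::write.csv(coupling[[mark]],
                       file.path(config$outDir,
                                 sprintf("coupling_%s.csv", mark)),
                       row.names = FALSE, quote = FALSE)
    for (key in names(edges))
      writeEdgeTable(edges[[key]],
                     file.path(config$outDir, sprintf("edges_%s.csv", key)),
                     jsonPath = file.path(config$outDir,
                                          sprintf("edges_%s.json", key)))
    writeStreamlines(filt$streamlines,
                     file.path(config$outDir, "streamlines_legit.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
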