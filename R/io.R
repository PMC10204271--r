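## Plain-text serialisation: TSV for events and electrode tables, long CSV
## for percent-change maps and ROI series, CSV for streamline vertices,
## CSV + frame-indexed JSON for edge tables. Headers state the units
## (ms relative to the mark, microvolts, mm).

.checkCols <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed file '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
}

#' Write / read an event set as TSV
#'
#' Columns: kind, onset_ms, offset_ms.
#'
#' @param events an \code{\link{EyeEventSet}}.
#' @param path file path.
#' @return \code{readEventSet} returns an \code{\link{EyeEventSet}};
#'   \code{writeEventSet} returns \code{path} invisibly.
#' @export
writeEventSet <- function(events, path) {
  write.table(eventTable(events), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeEventSet
#' @export
readEventSet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .checkCols(df, c("kind", "onset_ms", "offset_ms"), path)
  if (nrow(df) && (!is.numeric(df$onset_ms) || !is.numeric(df$offset_ms)))
    stop(sprintf("malformed file '%s': non-numeric onset/offset", path))
  new("EyeEventSet", events = df, insufficient = FALSE, minPerKind = 0)
}

#' Write / read an electrode table as TSV
#'
#' Columns: site_id, patient_id, roi, hemisphere, type, x_mm, y_mm, z_mm,
#' flat_x_mm, flat_y_mm, excluded, exclusion_reason.
#'
#' @param channels channel metadata data.frame.
#' @param path file path.
#' @export
writeElectrodeTable <- function(channels, path) {
  write.table(channels, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeElectrodeTable
#' @export
readElectrodeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .checkCols(df, REQUIRED_CHANNEL_COLS, path)
  df$excluded <- as.logical(df$excluded)
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  if (anyNA(df$excluded))
    stop(sprintf("malformed file '%s': non-logical 'excluded' flag", path))
  df
}

#' Write / read a percent-change map as long CSV
#'
#' Columns: site, band, mark, time_ms, pct_change, n_trials.
#'
#' @param pcm a \code{\link{PercentChangeMap}}.
#' @param path file path.
#' @export
writePercentChangeMap <- function(pcm, path) {
  m <- pctValues(pcm)
  df <- data.frame(site = rep(rownames(m), times = ncol(m)),
                   band = pcm@band, mark = pcm@mark,
                   time_ms = rep(binTimes(pcm), each = nrow(m)),
                   pct_change = as.vector(m), n_trials = pcm@nTrials,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePercentChangeMap
#' @export
readPercentChangeMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("site", "band", "mark", "time_ms", "pct_change",
                   "n_trials"), path)
  sites <- unique(df$site)
  times <- sort(unique(df$time_ms))
  m <- matrix(NA_real_, length(sites), length(times),
              dimnames = list(sites, NULL))
  m[cbind(match(df$site, sites), match(df$time_ms, times))] <- df$pct_change
  if (anyNA(m))
    stop(sprintf("malformed file '%s': incomplete site x time grid", path))
  new("PercentChangeMap", pct = m, band = df$band[1], mark = df$mark[1],
      timeMs = times, baselineMs = c(-600, -200), analysisMs = c(-200, 2000),
      nTrials = as.integer(df$n_trials[1]), droppedEvents = 0L)
}

#' Write a ROI series as long CSV
#'
#' Columns: roi, hemisphere, band, mark, time_ms, mean, lo, hi, sig_aug,
#' sig_att, n_sites.
#'
#' @param roiSeries a \code{\link{ROISeries}}.
#' @param path file path.
#' @export
writeRoiSeries <- function(roiSeries, path) {
  utils::write.csv(seriesTable(roiSeries), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read streamlines as a vertex CSV
#'
#' Columns: streamline_id, point (vertex order), x_mm, y_mm, z_mm, qa. The
#' reader validates the grid and errors on truncated or malformed files
#' rather than silently returning a partial set.
#'
#' @param sset a \code{\link{StreamlineSet}}.
#' @param path file path.
#' @export
writeStreamlines <- function(sset, path) {
  rows <- lapply(seq_along(sset@lines), function(i) {
    pts <- sset@lines[[i]]
    data.frame(streamline_id = sset@ids[i], point = seq_len(nrow(pts)),
               x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
               qa = sset@qa[[i]], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeStreamlines
#' @param masks optional mask list to attach to the read set.
#' @export
readStreamlines <- function(path, masks = list()) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 warning = function(w)
                   stop(sprintf("malformed file '%s': %s", path,
                                conditionMessage(w))))
  .checkCols(df, c("streamline_id", "point", "x_mm", "y_mm", "z_mm", "qa"),
             path)
  num <- c("point", "x_mm", "y_mm", "z_mm", "qa")
  bad <- !vapply(df[num], is.numeric, logical(1))
  if (any(bad) || anyNA(df[num]))
    stop(sprintf("malformed file '%s': non-numeric or missing values in %s",
                 path, paste(num[bad], collapse = ", ")))
  ids <- unique(df$streamline_id)
  lines <- list(); qa <- list()
  for (id in ids) {
    d <- df[df$streamline_id == id, , drop = FALSE]
    d <- d[order(d$point), , drop = FALSE]
    if (nrow(d) < 2L ||
        !identical(as.numeric(d$point), as.numeric(seq_len(nrow(d)))))
      stop(sprintf("malformed file '%s': streamline '%s' truncated (points %s)",
                   path, id, paste(range(d$point), collapse = "..")))
    lines[[length(lines) + 1L]] <- unname(as.matrix(d[, c("x_mm", "y_mm",
                                                          "z_mm")]))
    qa[[length(qa) + 1L]] <- d$qa
  }
  new("StreamlineSet", lines = lines, qa = qa, ids = as.character(ids),
      masks = masks)
}

#' Write a dynamic edge table as CSV and frame-indexed JSON
#'
#' The CSV has one row per edge (roi_a, roi_b, band, polarity, t_start_ms,
#' t_end_ms, n_streamlines); the JSON groups active edges per time frame for
#' animation front-ends.
#'
#' @param edgeTab a \code{\link{DynamicEdgeTable}}.
#' @param path CSV path.
#' @param jsonPath optional JSON path; NULL skips the JSON.
#' @param frameMs frame step for the JSON index.
#' @export
writeEdgeTable <- function(edgeTab, path, jsonPath = NULL, frameMs = 25) {
  ed <- edgeTable(edgeTab)
  utils::write.csv(ed, path, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath)) {
    if (nrow(ed)) {
      frames <- seq(min(ed$t_start_ms), max(ed$t_end_ms), by = frameMs)
      fr <- lapply(frames, function(f) {
        act <- ed[ed$t_start_ms <= f & ed$t_end_ms >= f, , drop = FALSE]
        list(time_ms = f,
             edges = if (nrow(act)) act[, c("roi_a", "roi_b", "band",
                                            "polarity")] else list())
      })
    } else fr <- list()
    jsonlite::write_json(fr, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(df, c("roi_a", "roi_b", "band", "polarity", "t_start_ms",
                   "t_end_ms", "n_streamlines"), path)
  new("DynamicEdgeTable", edges = df, droppedNoAdjacency = 0L)
}
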