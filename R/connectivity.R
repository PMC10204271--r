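## Sustained co-modulation between ROI pairs, its analytic chance
## probability, streamline legitimacy filtering, and the streamline-gated
## dynamic edge table.

#' Significance-mask matrix from a ROI series
#'
#' @param roiSeries a \code{\link{ROISeries}}.
#' @return integer matrix ROIs x bins with +1 (significant augmentation),
#'   -1 (attenuation) or 0; rownames are "hemisphere roi" keys, and the
#'   bin-centre times are attached as attribute \code{timesMs}.
#' @export
significanceMasks <- function(roiSeries) {
  tb <- seriesTable(roiSeries)
  keys <- unique(paste(tb$hemisphere, tb$roi))
  times <- sort(unique(tb$time_ms))
  m <- matrix(0L, length(keys), length(times),
              dimnames = list(keys, NULL))
  for (k in keys) {
    sel <- paste(tb$hemisphere, tb$roi) == k
    ord <- order(tb$time_ms[sel])
    m[k, ] <- (tb$sig_aug[sel][ord] - tb$sig_att[sel][ord])
  }
  attr(m, "timesMs") <- times
  m
}

#' Find sustained same-polarity co-modulation epochs between ROI pairs
#'
#' For every unordered ROI pair, emits a co-modulation epoch wherever both
#' masks carry the same polarity for at least \code{minRun} consecutive
#' bins; overlapping qualifying windows are merged into maximal epochs.
#'
#' @param masks integer matrix ROIs x bins with values +1/0/-1 (rownames are
#'   ROI keys), e.g. from \code{\link{significanceMasks}}.
#' @param timesMs bin-centre times (defaults to the matrix's
#'   \code{timesMs} attribute).
#' @param minRun minimum consecutive co-significant bins (default 8: 200 ms
#'   of 25 ms bins, or 40 ms of 5 ms bins).
#' @return data.frame(roi_a, roi_b, polarity, t_start_ms, t_end_ms, n_bins)
#'   with polarity "co-augmentation" or "co-attenuation".
#' @export
findComodulation <- function(masks, timesMs = attr(masks, "timesMs"),
                             minRun = 8) {
  stopifnot(is.matrix(masks), !is.null(rownames(masks)),
            length(timesMs) == ncol(masks))
  out <- list()
  nR <- nrow(masks)
  if (nR >= 2) {
    for (i in seq_len(nR - 1)) {
      for (j in (i + 1):nR) {
        for (pol in c(1L, -1L)) {
          joint <- masks[i, ] == pol & masks[j, ] == pol
          r <- rle(joint)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          hit <- which(r$values & r$lengths >= minRun)
          for (h in hit) {
            out[[length(out) + 1L]] <- data.frame(
              roi_a = rownames(masks)[i], roi_b = rownames(masks)[j],
              polarity = if (pol > 0) "co-augmentation" else "co-attenuation",
              t_start_ms = timesMs[starts[h]], t_end_ms = timesMs[ends[h]],
              n_bins = r$lengths[h], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(roi_a = character(), roi_b = character(),
                      polarity = character(), t_start_ms = numeric(),
                      t_end_ms = numeric(), n_bins = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$t_start_ms, res$roi_a, res$roi_b), , drop = FALSE]
}

#' Analytic chance probability of sustained co-modulation
#'
#' Type I error model for observing same-polarity co-modulation lasting at
#' least \code{minRun} bins at one or more of the nRois(nRois-1)/2 ROI pairs
#' across the nBins - minRun + 1 window starts, when each ROI is
#' independently significant in a fraction \code{chi} of bins: pair count
#' times window-start count times the joint probability that both ROIs of a
#' pair are significant at all \code{minRun} bins of a window
#' (chi^minRun per ROI).
#'
#' @param nRois ROI count (default 52).
#' @param nBins analysis bin count (89 for alpha, 441 for high gamma).
#' @param minRun minimum run in bins (default 8).
#' @param chi per-ROI fraction of significant bins, in [0, 1].
#' @return the chance probability.
#' @export
chanceProbability <- function(nRois = 52, nBins = 89, minRun = 8, chi) {
  stopifnot(nRois >= 2, minRun >= 1, minRun <= nBins)
  if (any(chi < 0 | chi > 1)) stop("chi must lie in [0, 1]")
  (nRois / 2) * (nRois - 1) * (nBins - minRun + 1) * chi^minRun * chi^minRun
}

#' Observed per-ROI significant-bin fraction
#'
#' The average, across ROIs, of the fraction of analysis bins carrying the
#' given polarity; the chi entering \code{\link{chanceProbability}}.
#'
#' @param masks matrix from \code{\link{significanceMasks}}.
#' @param polarity +1 for augmentation, -1 for attenuation.
#' @return fraction in [0, 1].
#' @export
observedChi <- function(masks, polarity = 1L) {
  mean(rowMeans(masks == polarity))
}

## segment lengths and turning angles of a polyline
.polyGeom <- function(pts) {
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  ang <- numeric(0)
  if (nrow(d) >= 2) {
    a <- d[-nrow(d), , drop = FALSE]; b <- d[-1, , drop = FALSE]
    cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  list(segLen = len, turnDeg = ang)
}

.inBox <- function(pts, box) {
  pts[, 1] >= box$min[1] & pts[, 1] <= box$max[1] &
  pts[, 2] >= box$min[2] & pts[, 2] <= box$max[2] &
  pts[, 3] >= box$min[3] & pts[, 3] <= box$max[3]
}

#' Filter streamlines for legitimacy
#'
#' Keeps a polyline iff its minimum per-vertex quantitative anisotropy is at
#' least \code{qaMin}, every vertex-to-vertex turning angle is at most
#' \code{maxTurnDeg}, its arc length lies in [\code{lenMinMm},
#' \code{lenMaxMm}], all vertices are inside the parenchyma mask (when one
#' is supplied) and outside every exclusion-mask box (brainstem, basal
#' ganglia, thalamus). Polylines with a coincident-vertex (degenerate)
#' segment are rejected with reason "degenerate".
#'
#' @param sset a \code{\link{StreamlineSet}}.
#' @param qaMin quantitative-anisotropy threshold (default 0.05).
#' @param maxTurnDeg maximum turning angle in degrees (default 70).
#' @param lenMinMm,lenMaxMm streamline length range in mm (default 10-250).
#' @return list(streamlines = legitimate \code{\link{StreamlineSet}},
#'   report = data.frame(id, kept, reason)).
#' @export
filterStreamlines <- function(sset, qaMin = 0.05, maxTurnDeg = 70,
                              lenMinMm = 10, lenMaxMm = 250) {
  stopifnot(is(sset, "StreamlineSet"))
  n <- length(sset@lines)
  kept <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    g <- .polyGeom(sset@lines[[i]])
    if (any(g$segLen == 0)) { reason[i] <- "degenerate"; next }
    len <- sum(g$segLen)
    if (len < lenMinMm || len > lenMaxMm) { reason[i] <- "length"; next }
    if (length(g$turnDeg) && max(g$turnDeg) > maxTurnDeg) {
      reason[i] <- "turning angle"; next
    }
    if (min(sset@qa[[i]]) < qaMin) { reason[i] <- "qa"; next }
    if (!is.null(sset@masks$parenchyma) &&
        !all(.inBox(sset@lines[[i]], sset@masks$parenchyma))) {
      reason[i] <- "parenchyma"; next
    }
    if (length(sset@masks$exclude)) {
      hit <- vapply(sset@masks$exclude,
                    function(b) any(.inBox(sset@lines[[i]], b)), logical(1))
      if (any(hit)) { reason[i] <- "exclusion mask"; next }
    }
    kept[i] <- TRUE
  }
  list(streamlines = new("StreamlineSet", lines = sset@lines[kept],
                         qa = sset@qa[kept], ids = sset@ids[kept],
                         masks = sset@masks),
       report = data.frame(id = sset@ids, kept = kept, reason = reason,
                           stringsAsFactors = FALSE))
}

#' ROI-pair adjacency from legitimate streamlines
#'
#' A pair is connected iff at least one streamline has one endpoint within
#' \code{captureRadiusMm} of each ROI centroid (nearest centroid wins);
#' streamlines with an endpoint outside every capture region, or with both
#' endpoints in one ROI, contribute nothing (their count is attached as
#' attribute \code{ignored}).
#'
#' @param sset a legitimate \code{\link{StreamlineSet}} (after
#'   \code{\link{filterStreamlines}}).
#' @param roiGeometry data.frame(roi, x_mm, y_mm, z_mm) of ROI centroids.
#' @param captureRadiusMm endpoint capture radius (default 3).
#' @return data.frame(roi_a, roi_b, n_streamlines), pairs sorted with
#'   roi_a < roi_b.
#' @export
pairAdjacency <- function(sset, roiGeometry, captureRadiusMm = 3) {
  stopifnot(is(sset, "StreamlineSet"),
            all(c("roi", "x_mm", "y_mm", "z_mm") %in% names(roiGeometry)))
  cent <- as.matrix(roiGeometry[, c("x_mm", "y_mm", "z_mm")])
  assign1 <- function(p) {
    d <- sqrt(colSums((t(cent) - p)^2))
    i <- which.min(d)
    if (d[i] <= captureRadiusMm) roiGeometry$roi[i] else NA_character_
  }
  pairs <- list(); ignored <- 0L
  for (i in seq_along(sset@lines)) {
    pts <- sset@lines[[i]]
    a <- assign1(pts[1, ]); b <- assign1(pts[nrow(pts), ])
    if (is.na(a) || is.na(b) || a == b) { ignored <- ignored + 1L; next }
    key <- paste(sort(c(a, b)), collapse = "\r")
    pairs[[key]] <- (if (is.null(pairs[[key]])) 0L else pairs[[key]]) + 1L
  }
  if (!length(pairs)) {
    res <- data.frame(roi_a = character(), roi_b = character(),
                      n_streamlines = integer(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(pairs), "\r", fixed = TRUE)
    res <- data.frame(roi_a = vapply(parts, `[[`, "", 1L),
                      roi_b = vapply(parts, `[[`, "", 2L),
                      n_streamlines = unlist(pairs, use.names = FALSE),
                      stringsAsFactors = FALSE)
    res <- res[order(res$roi_a, res$roi_b), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "ignored") <- ignored
  res
}

#' Streamline-gated dynamic edge table
#'
#' One edge per co-modulation epoch whose ROI pair has at least one
#' legitimate streamline: co-augmentation maps to "strengthened",
#' co-attenuation to "weakened" functional connectivity. Epochs whose pair
#' lacks adjacency are dropped and counted.
#'
#' @param epochs data.frame from \code{\link{findComodulation}}.
#' @param adjacency data.frame from \code{\link{pairAdjacency}}.
#' @param band band label stored on each edge.
#' @return A \code{\link{DynamicEdgeTable}}.
#' @export
buildDynamicEdges <- function(epochs, adjacency, band = "alpha") {
  adjKey <- paste(pmin(adjacency$roi_a, adjacency$roi_b),
                  pmax(adjacency$roi_a, adjacency$roi_b))
  if (!nrow(epochs)) {
    return(new("DynamicEdgeTable",
               edges = data.frame(roi_a = character(), roi_b = character(),
                                  band = character(), polarity = character(),
                                  t_start_ms = numeric(), t_end_ms = numeric(),
                                  n_streamlines = integer(),
                                  stringsAsFactors = FALSE),
               droppedNoAdjacency = 0L))
  }
  epKey <- paste(pmin(epochs$roi_a, epochs$roi_b),
                 pmax(epochs$roi_a, epochs$roi_b))
  hit <- match(epKey, adjKey)
  keep <- !is.na(hit)
  if (!any(keep)) {
    return(new("DynamicEdgeTable",
               edges = data.frame(roi_a = character(), roi_b = character(),
                                  band = character(), polarity = character(),
                                  t_start_ms = numeric(), t_end_ms = numeric(),
                                  n_streamlines = integer(),
                                  stringsAsFactors = FALSE),
               droppedNoAdjacency = as.integer(sum(!keep))))
  }
  edges <- data.frame(
    roi_a = pmin(epochs$roi_a, epochs$roi_b)[keep],
    roi_b = pmax(epochs$roi_a, epochs$roi_b)[keep],
    band = band,
    polarity = ifelse(epochs$polarity[keep] == "co-augmentation",
                      "strengthened", "weakened"),
    t_start_ms = epochs$t_start_ms[keep],
    t_end_ms = epochs$t_end_ms[keep],
    n_streamlines = adjacency$n_streamlines[hit[keep]],
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("DynamicEdgeTable", edges = edges,
      droppedNoAdjacency = as.integer(sum(!keep)))
}
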