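## Alpha/high-gamma temporal coupling on the 25 ms epoch grid.

#' Aggregate a 5 ms high-gamma series onto the 25 ms epoch grid
#'
#' Each 25 ms epoch value is the mean of the 5 ms bins whose centres fall
#' within +/- 12.5 ms of the epoch centre (5 bins in the interior, fewer at
#' the grid edges).
#'
#' @param gammaPct percent-change values on the 5 ms grid.
#' @param gammaTimesMs 5 ms bin-centre times.
#' @param alphaTimesMs 25 ms bin-centre times (default the 89-centre
#'   analysis grid).
#' @return numeric vector, one value per 25 ms epoch.
#' @export
aggregateGammaToEpochs <- function(gammaPct, gammaTimesMs,
                                   alphaTimesMs = seq(-200, 2000, by = 25)) {
  stopifnot(length(gammaPct) == length(gammaTimesMs))
  stepG <- unique(round(diff(gammaTimesMs), 9))
  stepA <- unique(round(diff(alphaTimesMs), 9))
  if (length(stepG) != 1L || length(stepA) != 1L ||
      stepA %% stepG != 0 ||
      !all(alphaTimesMs %in% gammaTimesMs))
    stop("misaligned grids: the 25 ms centres must lie on the 5 ms grid")
  half <- stepA / 2
  vapply(alphaTimesMs, function(ct) {
    mean(gammaPct[abs(gammaTimesMs - ct) <= half])
  }, numeric(1))
}

#' Pearson coupling between alpha and high-gamma percent-change series
#'
#' Standard Pearson r over the epoch grid with the two-sided p-value from
#' the exact t transform on n - 2 degrees of freedom. A negative r supports
#' the hypothesis that alpha augmentation co-occurs with high-gamma
#' attenuation (and alpha attenuation with high-gamma augmentation).
#'
#' @param alphaPct,gammaPct equal-length finite series (length >= 3).
#' @return list(r, p, n, flagged); \code{flagged} is TRUE (with r = NA) when
#'   either series has zero variance.
#' @export
pearsonAlphaGamma <- function(alphaPct, gammaPct) {
  stopifnot(length(alphaPct) == length(gammaPct), length(alphaPct) >= 3,
            all(is.finite(alphaPct)), all(is.finite(gammaPct)))
  if (sd(alphaPct) == 0 || sd(gammaPct) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(alphaPct),
                flagged = TRUE))
  ct <- cor.test(alphaPct, gammaPct, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(alphaPct),
       flagged = FALSE)
}

#' Per-ROI alpha/high-gamma coupling table
#'
#' Joins the per-ROI mean alpha series (25 ms grid) with the aggregated
#' high-gamma series and reports Pearson r and p per (ROI, hemisphere).
#'
#' @param alphaSeries \code{\link{ROISeries}} for the alpha band.
#' @param gammaSeries \code{\link{ROISeries}} for the high-gamma band at the
#'   same mark.
#' @return data.frame(roi, hemisphere, mark, r, p, n).
#' @export
couplingTable <- function(alphaSeries, gammaSeries) {
  at <- seriesTable(alphaSeries); gt <- seriesTable(gammaSeries)
  stopifnot(all(at$band == "alpha"), all(gt$band == "high_gamma"))
  mark <- unique(at$mark)
  stopifnot(length(mark) == 1L, identical(unique(gt$mark), mark))
  keys <- unique(at[, c("roi", "hemisphere")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    ai <- at$roi == keys$roi[i] & at$hemisphere == keys$hemisphere[i]
    gi <- gt$roi == keys$roi[i] & gt$hemisphere == keys$hemisphere[i]
    if (!any(gi)) next
    g25 <- aggregateGammaToEpochs(gt$mean[gi], gt$time_ms[gi],
                                  at$time_ms[ai])
    r <- pearsonAlphaGamma(at$mean[ai], g25)
    out[[length(out) + 1L]] <- data.frame(
      roi = keys$roi[i], hemisphere = keys$hemisphere[i], mark = mark,
      r = r$r, p = r$p, n = r$n, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(roi = character(), hemisphere = character(),
                      mark = character(), r = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
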