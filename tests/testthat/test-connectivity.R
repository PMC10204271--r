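test_that("chance model limits and monotonicity behave analytically", {
  expect_equal(chanceProbability(52, 89, 8, 0), 0)
  expect_equal(chanceProbability(52, 89, 8, 1), 26 * 51 * 82)
  expect_error(chanceProbability(52, 89, 8, 1.2), "chi")
  chis <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(chanceProbability(chi = chis)) > 0))
  expect_true(all(diff(vapply(c(10, 20, 52), function(R)
    chanceProbability(R, 89, 8, 0.3), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(89, 200, 441), function(T)
    chanceProbability(52, T, 8, 0.3), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(4, 8, 12), function(L)
    chanceProbability(52, 89, L, 0.3), numeric(1))) < 0))
})

test_that("co-modulation windows merge into maximal epochs", {
  times <- seq(-200, 2000, by = 25)
  m <- matrix(0L, 2, length(times), dimnames = list(c("A", "B"), NULL))
  ## disjoint significance: nothing
  m["A", 1:10] <- 1L; m["B", 30:40] <- 1L
  expect_equal(nrow(findComodulation(m, times)), 0)
  ## overlap of exactly 8 bins
  m[] <- 0L; m["A", 10:25] <- 1L; m["B", 18:40] <- 1L
  ep <- findComodulation(m, times)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_bins, 8)
  expect_equal(ep$t_start_ms, times[18])
  expect_equal(ep$t_end_ms, times[25])
  expect_equal(ep$polarity, "co-augmentation")
  ## opposite polarities never pair
  m[] <- 0L; m["A", 10:25] <- 1L; m["B", 10:25] <- -1L
  expect_equal(nrow(findComodulation(m, times)), 0)
})

test_that("co-modulation equals the brute-force scan on random masks", {
  times <- seq(-200, 2000, by = 25)
  set.seed(33)
  for (rep in 1:20) {
    m <- matrix(sample(c(-1L, 0L, 1L), 8 * length(times), replace = TRUE,
                       prob = c(0.25, 0.4, 0.35)),
                8, length(times), dimnames = list(LETTERS[1:8], NULL))
    expect_equal(findComodulation(m, times), bruteComod(m, times),
                 ignore_attr = TRUE)
  }
})

test_that("streamline legitimacy filtering enforces every criterion and is idempotent", {
  straight <- function(len, n = 21, y = 0)
    cbind(seq(0, len, length.out = n), y, 0)
  mk <- function(lines, qa, ids, masks = list())
    new("StreamlineSet", lines = lines, qa = qa, ids = ids, masks = masks)
  box <- list(min = c(40, -5, -5), max = c(60, 5, 5))
  bend <- rbind(c(0, 0, 0), c(20, 0, 0),
                c(20 + 20 * cos(80 * pi / 180), 20 * sin(80 * pi / 180), 0))
  ss <- mk(list(straight(100, y = 20), straight(5), straight(300), bend,
                straight(100, y = 20), rbind(c(0, 0, 0), c(0, 0, 0),
                                             c(10, 0, 0)),
                cbind(seq(30, 70, length.out = 9), 0, 0)),
           list(rep(0.10, 21), rep(0.10, 21), rep(0.10, 21), rep(0.10, 3),
                c(rep(0.10, 10), 0.02, rep(0.10, 10)), rep(0.10, 3),
                rep(0.10, 9)),
           c("ok", "short", "long", "bend", "lowqa", "degen", "masked"),
           masks = list(parenchyma = list(min = c(-500, -500, -500),
                                          max = c(500, 500, 500)),
                        exclude = list(box)))
  f <- filterStreamlines(ss)
  expect_equal(f$report$kept, c(TRUE, rep(FALSE, 6)))
  expect_equal(f$report$reason[f$report$id == "short"], "length")
  expect_equal(f$report$reason[f$report$id == "long"], "length")
  expect_equal(f$report$reason[f$report$id == "bend"], "turning angle")
  expect_equal(f$report$reason[f$report$id == "lowqa"], "qa")
  expect_equal(f$report$reason[f$report$id == "degen"], "degenerate")
  expect_equal(f$report$reason[f$report$id == "masked"], "exclusion mask")
  ## idempotence
  f2 <- filterStreamlines(f$streamlines)
  expect_identical(f2$streamlines@lines, f$streamlines@lines)
  expect_true(all(f2$report$kept))
  ## a 69 degree bend passes
  bend69 <- rbind(c(0, 0, 0), c(20, 0, 0),
                  c(20 + 20 * cos(69 * pi / 180), 20 * sin(69 * pi / 180), 0))
  f69 <- filterStreamlines(mk(list(bend69), list(rep(0.1, 3)), "b69"))
  expect_true(f69$report$kept)
})

test_that("generator streamline labels agree with the legitimacy filter", {
  cfg <- smallConfig(sitesPerRoi = 2,
                     rois = c("lateral_occipital", "pericalcarine",
                              "fusiform"))
  g <- roiGeometryFromChannels(cfg@channelTable)
  sl <- synthesizeStreamlines(g, cfg)
  f <- filterStreamlines(sl$streamlines)
  expect_equal(f$report$kept[match(sl$labels$id, f$report$id)],
               sl$labels$valid)
  bad <- !sl$labels$valid
  expect_equal(f$report$reason[match(sl$labels$id[bad], f$report$id)],
               sl$labels$violation[bad])
  ## adjacency over the legitimate subset equals the ground-truth pair set
  adj <- pairAdjacency(f$streamlines, g)
  truthPairs <- sort(paste(pmin(sl$labels$roi_a, sl$labels$roi_b),
                           pmax(sl$labels$roi_a, sl$labels$roi_b))[sl$labels$valid])
  expect_equal(sort(paste(adj$roi_a, adj$roi_b)), truthPairs)
})

test_that("endpoint capture builds pairs only across distinct ROIs", {
  g <- data.frame(roi = c("A", "B"), x_mm = c(0, 100), y_mm = 0, z_mm = 0,
                  stringsAsFactors = FALSE)
  line <- function(a, b) rbind(a, (a + b) / 2, b)
  ss <- new("StreamlineSet",
            lines = list(line(c(0, 0, 0), c(100, 0, 0)),
                         line(c(0, 0, 0), c(1, 1, 0)),
                         line(c(50, 50, 0), c(100, 0, 0))),
            qa = list(rep(0.1, 3), rep(0.1, 3), rep(0.1, 3)),
            ids = c("ab", "aa", "stray"), masks = list())
  adj <- pairAdjacency(ss, g)
  expect_equal(nrow(adj), 1)
  expect_equal(c(adj$roi_a, adj$roi_b), c("A", "B"))
  expect_equal(adj$n_streamlines, 1)
  expect_equal(attr(adj, "ignored"), 2)
})

test_that("dynamic edges require both co-modulation and a streamline", {
  epochs <- data.frame(
    roi_a = c("A", "A", "B"), roi_b = c("B", "C", "C"),
    polarity = c("co-augmentation", "co-attenuation", "co-augmentation"),
    t_start_ms = c(0, 100, 200), t_end_ms = c(175, 275, 375),
    n_bins = 8L, stringsAsFactors = FALSE)
  adj <- data.frame(roi_a = c("A", "B"), roi_b = c("C", "C"),
                    n_streamlines = c(3L, 1L), stringsAsFactors = FALSE)
  et <- buildDynamicEdges(epochs, adj, band = "alpha")
  ed <- edgeTable(et)
  ## the co-augmenting A-B pair has no streamline: dropped and counted
  expect_equal(nrow(ed), 2)
  expect_equal(et@droppedNoAdjacency, 1L)
  expect_setequal(paste(ed$roi_a, ed$roi_b), c("A C", "B C"))
  expect_equal(ed$polarity[paste(ed$roi_a, ed$roi_b) == "A C"], "weakened")
  expect_equal(ed$polarity[paste(ed$roi_a, ed$roi_b) == "B C"], "strengthened")
  expect_equal(ed$n_streamlines[paste(ed$roi_a, ed$roi_b) == "A C"], 3L)
})
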