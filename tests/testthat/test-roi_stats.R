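test_that("site selection drops excluded sites and under-sampled ROIs", {
  ch <- defaultChannelTable(sitesPerRoi = 4,
                            rois = c("lateral_occipital", "pericalcarine"))
  ## knock one pericalcarine site out on the left: 3 clean sites -> dropped
  i <- which(ch$roi == "pericalcarine" & ch$hemisphere == "L")[1]
  ch$excluded[i] <- TRUE; ch$exclusion_reason[i] <- "seizure-onset zone"
  sel <- selectAnalysisSites(ch, minSites = 4)
  expect_false(any(sel$sites$excluded))
  keys <- paste(sel$rois$hemisphere, sel$rois$roi)
  expect_setequal(keys, c("L lateral_occipital", "R lateral_occipital",
                          "R pericalcarine"))
  ## all clean: identity
  sel2 <- selectAnalysisSites(defaultChannelTable(), minSites = 4)
  expect_equal(nrow(sel2$rois), 10)
  expect_error(selectAnalysisSites(ch[0, ]), "empty")
})

test_that("studentized bootstrap handles degenerate input and brackets the mean", {
  ci <- studentizedBootstrap(rep(7, 12), level = 0.95, nResamples = 1000)
  expect_equal(unname(ci), c(7, 7, 7))
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(15, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    ci <- studentizedBootstrap(v, level = 0.99, nResamples = 1000, seed = i)
    expect_lte(ci["lower"], ci["mean"])
    expect_gte(ci["upper"], ci["mean"])
    expect_equal(unname(ci["mean"]), mean(v))
  }
})

test_that("run-length rule keeps >= minRun runs only and reports onsets", {
  times <- seq(-200, 2000, by = 25)
  n <- length(times)
  lower <- rep(-1, n); upper <- rep(1, n)
  ## exactly 8 bins above zero starting at bin 20
  lower[20:27] <- 0.5
  r <- detectSignificantRuns(lower, upper, times, minRun = 8)
  expect_equal(sum(r$aug), 8)
  expect_equal(r$onsetAugMs, times[20])
  ## 7 bins: nothing
  lower7 <- rep(-1, n); lower7[20:26] <- 0.5
  r7 <- detectSignificantRuns(lower7, upper, times, minRun = 8)
  expect_false(any(r7$aug))
  expect_true(is.na(r7$onsetAugMs))
  ## bounds straddling zero everywhere: empty masks
  r0 <- detectSignificantRuns(rep(-1, n), rep(1, n), times)
  expect_false(any(r0$aug) || any(r0$att))
  ## attenuation side
  upperA <- rep(1, n); upperA[30:45] <- -0.2
  rA <- detectSignificantRuns(rep(-1, n), upperA, times)
  expect_equal(sum(rA$att), 16)
  expect_equal(rA$onsetAttMs, times[30])
})

test_that("widening the CI level shrinks the significance masks", {
  set.seed(8)
  mat <- matrix(rnorm(8 * 89, mean = 2, sd = 4), nrow = 8)
  c99 <- bootstrapCISeries(mat, level = 0.99, nResamples = 3000, seed = 1)
  c9999 <- bootstrapCISeries(mat, level = 0.9999, nResamples = 3000, seed = 1)
  m99 <- c99$lower > 0
  m9999 <- c9999$lower > 0
  expect_true(all(m99 | !m9999))   # 99% mask contains the 99.99% mask
})

test_that("shell profiles follow the interpolation and grouping geometry", {
  grid25 <- seq(-1000, 2000, by = 25)
  ch <- data.frame(site_id = c("e1", "e2"), patient_id = "p", roi = "r",
                   hemisphere = "L", type = "ieeg", excluded = FALSE,
                   exclusion_reason = "", x_mm = 0, y_mm = 0, z_mm = 0,
                   flat_x_mm = c(-20, 20), flat_y_mm = c(-5, -25),
                   stringsAsFactors = FALSE)
  pcm <- constantPcm(c("e1", "e2"), c(10, 30))
  ## mesh points colocated with the electrodes: shells 0-10 and 20-30 get
  ## the electrode values, 10-20 has no mesh point at all
  mesh <- data.frame(flat_x_mm = c(-20, 20), flat_y_mm = c(-5, -25))
  sp <- distanceShellProfile(pcm, ch, mesh, nResamples = 500)
  v010 <- unique(sp$value[sp$shell == "Ventral_0-10mm"])
  v2030 <- unique(sp$value[sp$shell == "Ventral_20-30mm"])
  expect_equal(v010, 10)
  expect_equal(v2030, 30)
  expect_false("Ventral_10-20mm" %in% sp$shell)
  ## single electrode, ventral at 5 mm: only Ventral_0-10 populated
  sp1 <- distanceShellProfile(constantPcm("e1", 10), ch[1, ],
                              mesh[1, , drop = FALSE], nResamples = 500)
  expect_setequal(unique(sp1$shell), "Ventral_0-10mm")
  ## mesh point 8 mm from both electrodes averages them
  ch2 <- ch; ch2$flat_x_mm <- c(-8, 8); ch2$flat_y_mm <- c(-5, -5)
  mesh2 <- data.frame(flat_x_mm = 0, flat_y_mm = -5)
  sp2 <- distanceShellProfile(pcm, ch2, mesh2, nResamples = 500)
  expect_equal(unique(sp2$value), 20)
  ## uncovered shell reported missing, not zero
  mesh3 <- data.frame(flat_x_mm = c(-20, 300), flat_y_mm = c(-5, -25))
  sp3 <- distanceShellProfile(pcm, ch, mesh3, nResamples = 500)
  expect_true(all(is.na(sp3$value[sp3$shell == "Ventral_20-30mm"])))
})

test_that("the 99.99% CI corresponds to a Bonferroni correction over 500 comparisons", {
  expect_equal(bonferroniComparisons(0.9999), 500)
})
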