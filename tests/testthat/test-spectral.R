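test_that("Gaussian kernel half-power duality matches the closed form", {
  fs <- 1000
  ## ln2/(2 pi t_h): 39.4 ms -> 2.8 Hz (2 s.f.), 7.9 ms -> 13.96 Hz
  expect_equal(signif(measureFreqHalfPower(designGaussianLowpass(39.4, fs), fs), 2),
               2.8)
  expect_equal(measureFreqHalfPower(designGaussianLowpass(7.9, fs), fs),
               log(2) / (2 * pi * 0.0079), tolerance = 1e-3)
  ## doubling t_h halves f_h
  r <- measureFreqHalfPower(designGaussianLowpass(20, fs), fs) /
       measureFreqHalfPower(designGaussianLowpass(40, fs), fs)
  expect_equal(r, 2, tolerance = 0.01)
  expect_equal(sum(designGaussianLowpass(39.4, fs)), 1)   # unit DC gain
  expect_error(designGaussianLowpass(1.5, fs), "sampling intervals")
})

test_that("demodulation recovers pure-tone amplitude independent of phase", {
  fs <- 1000
  k <- designGaussianLowpass(39.4, fs)
  t <- (0:9999) / fs
  expect_true(all(demodulate(rep(0, 10000), fs, 10, k) == 0))
  steady <- 2000:8000
  amps <- vapply(c(0, 1, 2.5, 4.7), function(ph) {
    mean(demodulate(sin(2 * pi * 10 * t + ph), fs, 10, k)[steady])
  }, numeric(1))
  expect_true(all(abs(amps - 1) < 0.01))
  expect_lt(max(amps) / min(amps) - 1, 0.01)
  ## tone offset by 3 half-power widths is suppressed to <= 0.05
  fh <- measureFreqHalfPower(k, fs)
  off <- demodulate(sin(2 * pi * (10 + 3 * fh) * t), fs, 10, k)
  expect_lte(mean(off[steady]), 0.05)
  expect_error(demodulate(rep(0, 50), fs, 10, k), "kernel longer")
})

test_that("epoch grids reproduce the printed bin counts", {
  for (spec in list(bandSpec("alpha"), bandSpec("high_gamma"))) {
    g <- epochGrid(spec$binMs)
    nAnalysis <- sum(g$centers >= -200 & g$centers <= 2000)
    expect_equal(nAnalysis, if (spec$band == "alpha") 89 else 441)
  }
})

test_that("percent change tracks amplitude steps and zeroes the baseline", {
  ## synthetic recording whose alpha amplitude steps 1.0 -> 1.5 at the mark
  fs <- 1000; n <- 40 * fs
  tS <- (0:(n - 1)) / fs
  onsets <- c(10000, 20000, 30000)
  env <- rep(1, n)
  for (o in onsets) env[tS * 1000 >= o & tS * 1000 <= o + 2500] <- 1.5
  ch <- defaultChannelTable(sitesPerRoi = 1, rois = "lateral_occipital")[c(1, 3), ]
  ch$type[2] <- "eog"
  sig <- cbind(env * sin(2 * pi * 10 * tS), rep(0, n))
  colnames(sig) <- ch$site_id
  rec <- new("Recording", signals = sig, samplingRate = fs, channels = ch)
  ev <- new("EyeEventSet",
            events = data.frame(kind = "closure", onset_ms = onsets,
                                offset_ms = onsets + 176),
            insufficient = TRUE, minPerKind = 16)
  pcm <- percentChangeMap(rec, ev, "alpha", "closure_onset")
  tm <- binTimes(pcm); v <- pctValues(pcm)[1, ]
  expect_lt(max(abs(v[tm >= 300 & tm <= 1800] - 50)), 2)  # post-mark plateau
  expect_equal(mean(v[tm >= -600 & tm <= -200]), 0)       # exact baseline zero
  ## global rescaling leaves the map unchanged
  rec10 <- new("Recording", signals = sig * 10, samplingRate = fs,
               channels = ch)
  pcm10 <- percentChangeMap(rec10, ev, "alpha", "closure_onset")
  expect_equal(pctValues(pcm10), pctValues(pcm), tolerance = 1e-10)
  ## constant amplitude: 0% everywhere
  recc <- new("Recording", signals = cbind(sin(2 * pi * 10 * tS), rep(0, n)),
              samplingRate = fs, channels = ch)
  colnames(recc@signals) <- ch$site_id
  pcmc <- percentChangeMap(recc, ev, "alpha", "closure_onset")
  expect_lt(max(abs(pctValues(pcmc))), 0.5)
})

test_that("offset-aligned epochs keep the baseline anchored to the onset", {
  fs <- 1000; n <- 40 * fs
  tS <- (0:(n - 1)) / fs
  onsets <- c(10000, 20000, 30000); offsets <- onsets + 500
  env <- rep(1, n)
  for (o in onsets) env[tS * 1000 >= o & tS * 1000 <= o + 3000] <- 1.5
  ch <- defaultChannelTable(sitesPerRoi = 1, rois = "lateral_occipital")[c(1, 3), ]
  ch$type[2] <- "eog"
  sig <- cbind(env * sin(2 * pi * 10 * tS), rep(0, n))
  colnames(sig) <- ch$site_id
  rec <- new("Recording", signals = sig, samplingRate = fs, channels = ch)
  ev <- new("EyeEventSet",
            events = data.frame(kind = "closure", onset_ms = onsets,
                                offset_ms = offsets),
            insufficient = TRUE, minPerKind = 16)
  pcm <- percentChangeMap(rec, ev, "alpha", "closure_offset")
  tm <- binTimes(pcm); v <- pctValues(pcm)[1, ]
  ## the whole offset-aligned analysis window sits after the onset step, so
  ## it must read +50% against the onset-anchored baseline
  expect_lt(max(abs(v[tm >= 300 & tm <= 1800] - 50)), 2)
})
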