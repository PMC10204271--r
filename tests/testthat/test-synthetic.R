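test_that("scheduled event durations match the printed medians and the 2 s rule", {
  cfg <- smallConfig(nEvents = 30, seed = 13)
  ev <- eventTable(scheduleEvents(cfg))
  expect_equal(nrow(ev), 60)
  durC <- ev$offset_ms[ev$kind == "closure"] - ev$onset_ms[ev$kind == "closure"]
  expect_lt(abs(median(durC) - 176), 20)
  ## exhaustive pairwise scan: no opposite-kind event within 2 s
  cl <- ev[ev$kind == "closure", ]; op <- ev[ev$kind == "opening", ]
  for (i in seq_len(nrow(cl)))
    for (j in seq_len(nrow(op))) {
      expect_gt(abs(cl$onset_ms[i] - op$onset_ms[j]), 2000)
      expect_gt(abs(cl$onset_ms[i] - op$offset_ms[j]), 2000)
      expect_gt(abs(cl$offset_ms[i] - op$onset_ms[j]), 2000)
    }
})

test_that("empty and infeasible schedules are handled explicitly", {
  expect_equal(nrow(eventTable(scheduleEvents(smallConfig(nEvents = 0)))), 0)
  cfg <- smallConfig(nEvents = 30, durationS = 20)
  expect_error(scheduleEvents(cfg), "infeasible")
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- smallConfig(nEvents = 3, seed = 11)
  ev1 <- scheduleEvents(cfg); ev2 <- scheduleEvents(cfg)
  expect_identical(eventTable(ev1), eventTable(ev2))
  r1 <- synthesizeRecording(cfg, ev1); r2 <- synthesizeRecording(cfg, ev2)
  expect_identical(signalMatrix(r1$recording), signalMatrix(r2$recording))
  g <- roiGeometryFromChannels(cfg@channelTable)
  s1 <- synthesizeStreamlines(g, cfg); s2 <- synthesizeStreamlines(g, cfg)
  expect_identical(s1$streamlines@lines, s2$streamlines@lines)
})

test_that("EOG deflections exceed 50 uV exactly within event intervals", {
  cfg <- smallConfig(nEvents = 4, seed = 2)
  ev <- scheduleEvents(cfg)
  rec <- synthesizeRecording(cfg, ev)$recording
  eog <- eogTrace(rec)
  tMs <- (seq_along(eog) - 1) / samplingRate(rec) * 1000
  evt <- eventTable(ev)
  inEvent <- rep(FALSE, length(eog))
  for (i in seq_len(nrow(evt)))
    inEvent[tMs >= evt$onset_ms[i] & tMs <= evt$offset_ms[i]] <- TRUE
  for (i in seq_len(nrow(evt)))
    expect_true(any(abs(eog[tMs >= evt$onset_ms[i] &
                            tMs <= evt$offset_ms[i]]) > 50))
  expect_true(all(abs(eog[!inEvent]) <= 50))
  ## one deflection per event
  expect_equal(eventCounts(detectEvents(
    highpassTimeConstant(eog, samplingRate(rec)), samplingRate(rec))),
    eventCounts(ev))
})

test_that("null modulation leaves band envelopes flat", {
  cfg <- smallConfig(nEvents = 20, seed = 5,
                     profiles = defaultModulationProfiles()[0, ])
  ev <- scheduleEvents(cfg)
  rec <- synthesizeRecording(cfg, ev)$recording
  pcm <- percentChangeMap(rec, ev, "alpha", "closure_onset")
  tm <- binTimes(pcm)
  inAnalysis <- tm >= -200 & tm <= 2000
  expect_true(all(abs(rowMeans(pctValues(pcm)[, inAnalysis])) < 3))
})

test_that("injected +50% alpha modulation is visible to an analytic-envelope oracle", {
  ## noiseless isolated alpha component; oracle = FFT analytic signal
  mp <- data.frame(roi = "lateral_occipital", band = "alpha",
                   kind = "closure", mark_edge = "onset", onset_ms = 50,
                   duration_ms = 1000, peak_pct = 50, ramp_ms = 100,
                   stringsAsFactors = FALSE)
  cfg <- smallConfig(nEvents = 5, seed = 3, profiles = mp,
                     rois = "lateral_occipital", noiseUv = 0, gammaBaseUv = 0)
  ev <- scheduleEvents(cfg)
  rec <- synthesizeRecording(cfg, ev)$recording
  x <- signalMatrix(rec)[, 1]
  env <- analyticEnvelope(x)
  tMs <- (seq_along(x) - 1) / samplingRate(rec) * 1000
  evt <- eventTable(ev)
  onsets <- evt$onset_ms[evt$kind == "closure"]
  inside <- outside <- rep(FALSE, length(x))
  for (o in onsets) {
    inside[tMs >= o + 150 & tMs <= o + 950] <- TRUE    # plateau only
    outside[tMs >= o - 900 & tMs <= o - 300] <- TRUE   # pre-event baseline
  }
  ratio <- mean(env[inside]) / mean(env[outside])
  expect_lt(abs(ratio - 1.50), 0.03)
})

test_that("ground-truth curves are exactly zero over the baseline window", {
  cfg <- smallConfig(nEvents = 3, seed = 9)
  truth <- synthesizeRecording(cfg, scheduleEvents(cfg))$truth
  cv <- truth@curves
  expect_gt(nrow(cv), 0)
  expect_true(all(cv$pct[cv$time_ms <= -200] == 0))
})

test_that("streamline fixtures carry the intended validity labels", {
  cfg <- smallConfig()
  g <- roiGeometryFromChannels(cfg@channelTable)
  sl <- synthesizeStreamlines(g, cfg)
  lab <- sl$labels
  expect_true(any(lab$valid))
  expect_setequal(lab$violation[!lab$valid],
                  c("length", "length", "turning angle", "qa",
                    "exclusion mask"))
  expect_error(synthesizeStreamlines(g[1, , drop = FALSE], cfg),
               "at least 2")
  ## profile referencing an unknown ROI is rejected
  mp <- defaultModulationProfiles()
  mp$roi[1] <- "no_such_roi"
  expect_error(simConfig(modulationProfiles = mp,
                         channelTable = smallChannelTable()),
               "channelTable")
})
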