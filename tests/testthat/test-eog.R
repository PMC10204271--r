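test_that("RC high-pass matches the closed-form step decay and rejects DC", {
  fs <- 1000
  ## 100 uV step at 2 s, RC = 1 s: e^-1 decay after one time constant
  x <- c(rep(0, 2 * fs), rep(100, 4 * fs))
  y <- highpassTimeConstant(x, fs, 1.0)
  expect_lt(abs(y[3 * fs + 1] - 100 * exp(-1)), 1)
  ## DC input decays below 1% after 5 RC
  dc <- rep(80, 7 * fs)
  ydc <- highpassTimeConstant(dc, fs, 1.0)
  expect_lt(abs(ydc[6 * fs]), 0.8)
  expect_identical(highpassTimeConstant(rep(0, 100), fs), rep(0, 100))
  expect_error(highpassTimeConstant(c(1, NA, 3), fs), "finite")
})

test_that("threshold detection finds supra-threshold deflections at the crossings", {
  fs <- 1000
  x <- rep(0, 10 * fs)
  x[3001:3200] <- 60                       # 60 uV closure deflection
  ev <- eventTable(detectEvents(x, fs, minPerKind = 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "closure")
  expect_lt(abs(ev$onset_ms - 3000), 2)    # crossing +/- 1 sample
  expect_lt(abs(ev$offset_ms - 3200), 2)
  ## below threshold: nothing
  x40 <- rep(0, 10 * fs); x40[3001:3200] <- 40
  expect_equal(nrow(eventTable(detectEvents(x40, fs))), 0)
  expect_error(detectEvents(x, fs, thresholdUv = 0), "positive")
})

test_that("opposite-kind events within 2 s are removed, and the rule is idempotent", {
  fs <- 1000
  x <- rep(0, 30 * fs)
  x[10001:10200] <- 60                     # closure at 10.0 s
  x[11501:11700] <- -60                    # opening at 11.5 s
  x[20001:20200] <- 60                     # isolated closure at 20 s
  es <- detectEvents(x, fs, minPerKind = 1)
  ev <- eventTable(es)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "closure")
  expect_gt(ev$onset_ms, 19000)
  ## surviving set is unchanged by re-applying the exclusion rule
  cl <- ev$onset_ms[ev$kind == "closure"]
  op <- ev$onset_ms[ev$kind == "opening"]
  if (length(cl) && length(op))
    expect_true(all(abs(outer(cl, op, "-")) > 2000))
})

test_that("detection recovers the generator schedule within 10 ms", {
  cfg <- smallConfig(nEvents = 5, seed = 4)
  ev <- scheduleEvents(cfg)
  rec <- synthesizeRecording(cfg, ev)$recording
  det <- detectEvents(highpassTimeConstant(eogTrace(rec), samplingRate(rec)),
                      samplingRate(rec))
  truth <- eventTable(ev); got <- eventTable(det)
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$kind, truth$kind)
  expect_true(all(abs(got$onset_ms - truth$onset_ms) <= 10))
})
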