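test_that("recording round trip preserves every numeric field and metadata", {
  set.seed(4)
  rec <- EMGRecording(emg = matrix(rnorm(2 * 5000), ncol = 2),
                      emgRate = 5000, channelLabels = c("LG", "MG"),
                      angle = runif(100, 0, 60), angleRate = 100,
                      subjectId = "S7", trialId = "T3",
                      phase = runif(100))
  stem <- file.path(withr::local_tempdir(), "rec")
  writeRecording(rec, stem)
  back <- readRecording(stem)
  expect_identical(emg(back), emg(rec))
  expect_identical(angleStream(back), angleStream(rec))
  expect_identical(back@phase, rec@phase)
  expect_identical(channelLabels(back), c("LG", "MG"))
  expect_identical(emgRate(back), 5000)
  expect_identical(angleRate(back), 100)
  expect_identical(back@subjectId, "S7")
  expect_identical(back@trialId, "T3")
})

test_that("malformed recordings are rejected with format errors", {
  dir <- withr::local_tempdir()
  rec <- EMGRecording(emg = matrix(rnorm(600), ncol = 6), emgRate = 100,
                      channelLabels = KNOWN_MUSCLES,
                      angle = runif(10), angleRate = 10)
  stem <- file.path(dir, "bad")
  writeRecording(rec, stem)

  # 6 data columns but only 5 labels in the sidecar
  meta <- jsonlite::fromJSON(paste0(stem, ".meta.json"))
  meta$channel_labels <- meta$channel_labels[1:5]
  jsonlite::write_json(meta, paste0(stem, ".meta.json"), auto_unbox = TRUE)
  expect_error(readRecording(stem), class = "fgcnnFormatError")

  # empty angle stream
  stem2 <- file.path(dir, "bad2")
  writeRecording(rec, stem2)
  writeLines("angle_deg", paste0(stem2, ".angle.csv"))
  expect_error(readRecording(stem2), class = "fgcnnFormatError")

  # missing sidecar entirely
  expect_error(readRecording(file.path(dir, "nothere")),
               class = "fgcnnFormatError")

  # non-positive rate
  stem3 <- file.path(dir, "bad3")
  writeRecording(rec, stem3)
  meta <- jsonlite::fromJSON(paste0(stem3, ".meta.json"))
  meta$emg_rate <- 0
  jsonlite::write_json(meta, paste0(stem3, ".meta.json"), auto_unbox = TRUE)
  expect_error(readRecording(stem3), class = "fgcnnFormatError")
})

test_that("band-pass filter passes in-band tones and rejects out-of-band", {
  fs <- 5000
  t <- seq(0, 1, by = 1 / fs)[-1]
  fftAmp <- function(x, f) {
    # amplitude of the tone at f Hz over the middle of the trace (edges
    # carry the forward-backward transient)
    mid <- x[(fs %/% 4):(3 * fs %/% 4)]
    2 * abs(sum(mid * exp(-2i * pi * f * (seq_along(mid) - 1) / fs))) /
      length(mid)
  }
  inBand <- sin(2 * pi * 100 * t)
  out <- bandpassFilter(inBand, fs, 10, 500)
  expect_equal(fftAmp(out, 100), fftAmp(inBand, 100), tolerance = 0.01)

  low <- sin(2 * pi * 2 * t)
  outLow <- bandpassFilter(low, fs, 10, 500)
  expect_lt(fftAmp(outLow, 2), 0.1 * fftAmp(low, 2))

  expect_identical(bandpassFilter(rep(0, 1000), fs, 10, 500), rep(0, 1000))
  expect_error(bandpassFilter(inBand, fs, 10, 2600),
               class = "fgcnnParameterError")
  expect_error(bandpassFilter(inBand, fs, 500, 10),
               class = "fgcnnParameterError")
})

test_that("repeated filtering is idempotent for an in-band signal", {
  fs <- 5000
  t <- seq_len(fs) / fs
  x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 200 * t)
  f1 <- bandpassFilter(x, fs, 10, 500)
  f2 <- bandpassFilter(f1, fs, 10, 500)
  mid <- (fs %/% 4):(3 * fs %/% 4)
  expect_lt(sqrt(mean((f2[mid] - f1[mid])^2)) / sqrt(mean(f1[mid]^2)), 0.02)
})

test_that("window segmentation matches the count formula and brute force", {
  seg <- segmentWindows(rnorm(5000), 5000, 50, 20)
  expect_identical(nrow(seg$windows), 48L)  # floor((5000-250)/100)+1

  x <- rnorm(250)
  one <- segmentWindows(x, 5000, 50, 20)
  expect_identical(nrow(one$windows), 1L)
  expect_identical(as.numeric(one$windows[1, ]), x)
  expect_error(segmentWindows(rnorm(249), 5000, 50, 20),
               class = "fgcnnEmptyInputError")

  # brute-force enumeration property over random geometries
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    step <- sample(1:15, 1)
    len <- n + sample(0:100, 1)
    x <- rnorm(len)
    seg <- segmentWindows(x, 1000, n, step)  # 1 kHz: ms == samples
    starts <- seq(1, len - n + 1, by = step)
    expect_identical(nrow(seg$windows), length(starts))
    k <- sample(length(starts), 1)
    expect_identical(as.numeric(seg$windows[k, ]),
                     x[starts[k]:(starts[k] + n - 1)])
    if (length(starts) > 1) {
      expect_true(all(diff(seg$endTimes) > 0))
    }
  }
})

test_that("angle targets are interpolated at window end times, no extrapolation", {
  expect_equal(alignTargets(c(0, 10), 100, 0.005), 5.0)
  expect_equal(alignTargets(c(0, 10, 4), 100, 0.01), 10.0)
  expect_error(alignTargets(c(0, 10), 100, 0.02),
               class = "fgcnnAlignmentError")
  # exact on piecewise-linear streams
  tA <- seq(0, 1, by = 0.01)
  angle <- 3 + 2 * tA
  ends <- runif(20, 0, 1)
  expect_equal(alignTargets(angle, 100, ends), 3 + 2 * ends,
               tolerance = 1e-12)
})

test_that("angle scaler maps extrema to [-1, 1] and round-trips", {
  sc <- fitAngleScaler(c(0, 60))
  expect_equal(scaleAngles(sc, 30), 0)
  expect_equal(scaleAngles(sc, c(0, 60)), c(-1, 1))
  expect_equal(unscaleAngles(sc, scaleAngles(sc, 17.3)), 17.3,
               tolerance = 1e-12)
  expect_error(fitAngleScaler(rep(5, 10)),
               class = "fgcnnDegenerateScaleError")
  # out-of-range values survive scaling but are clipped on inversion
  expect_gt(scaleAngles(sc, 70), 1)
  expect_equal(unscaleAngles(sc, scaleAngles(sc, 70)), 60)
  expect_equal(unscaleAngles(sc, scaleAngles(sc, 70), clip = FALSE), 70)
})

test_that("windowRecording wires filtering, segmentation and alignment", {
  rec <- generateTrial(smallGaitConfig(), 1)
  ds <- windowRecording(rec, "LG")
  expect_s4_class(ds, "WindowedDataset")
  expect_identical(ncol(windowsMatrix(ds)), 250L)
  expect_identical(nWindows(ds), (40000L - 250L) %/% 100L + 1L)
  expect_true(all(diff(ds@windowEndTimes) > 0))
  expect_error(windowRecording(rec, "XX"), class = "fgcnnParameterError")
})
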