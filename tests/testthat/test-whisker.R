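test_that("a static video gives a flat (zero-motion) energy trace", {
  vid <- synthWhiskerVideo(n_frames = 30, deflection = rep(0, 30))
  tr <- motionEnergy(vid$frames, stim_onset_frame = 20,
                     stim_duration_frames = 5)
  expect_lt(diff(range(traceValues(tr))), 1e-12)
  norm <- normalizeTrace(tr, pre_window_s = 0.5)
  expect_equal(traceValues(norm), rep(0, 30), tolerance = 1e-12)
  expect_error(motionEnergy(vid$frames[, , 1, drop = FALSE]),
               "at least 2 frames")
})

test_that("motion energy rises when the filament moves", {
  defl <- c(rep(0, 30), 6 * sin(2 * pi * 8 * (1:30) / 30), rep(0, 30))
  vid <- synthWhiskerVideo(n_frames = 90, deflection = defl)
  tr <- traceValues(motionEnergy(vid$frames, stim_onset_frame = 31))
  expect_gt(mean(tr[35:56]), 10 * mean(tr[5:26]))
})

test_that("motion energy tracks a frame-difference oracle on noisy video", {
  s <- rngStream(77)
  defl <- c(rep(0, 20), cumsum(rnorm(40)), rep(0, 20))
  vid <- synthWhiskerVideo(n_frames = 80, deflection = defl,
                           noise_sd = 0.02, stream = s)
  me <- traceValues(motionEnergy(vid$frames))
  oracle <- frameDiffEnergy(vid$frames)
  expect_gt(cor(me, oracle, method = "spearman"), 0.8)
})

test_that("baseline normalization averages the low 20th percentile", {
  tr <- MotionTrace(c(1:10, 5, 5), frame_rate_hz = 30,
                    stim_onset_frame = 11)
  # pre-window of 10 frames (1/3 s): values 1..10, low-20% subset {1, 2}
  norm <- normalizeTrace(tr, pre_window_s = 10 / 30)
  expect_equal(traceValues(norm), c(1:10, 5, 5) - 1.5)
  expect_true(norm@normalized)

  # constant trace: all zeros after normalization
  const <- MotionTrace(rep(7, 40), stim_onset_frame = 40)
  expect_equal(traceValues(normalizeTrace(const, 1.2)), rep(0, 40))

  # shift invariance
  shifted <- MotionTrace(c(1:10, 5, 5) + 123, frame_rate_hz = 30,
                         stim_onset_frame = 11)
  expect_equal(traceValues(normalizeTrace(shifted, 10 / 30)),
               traceValues(norm))

  expect_error(normalizeTrace(MotionTrace(1:10, stim_onset_frame = 5), 1.2),
               "insufficient pre-stimulus")
})

test_that("the whisking threshold is mean + 3 SD of the baseline", {
  z <- MotionTrace(rep(0, 50), stim_onset_frame = 40, normalized = TRUE)
  expect_equal(whiskingThreshold(z, 1.2), 0)

  s <- rngStream(13)
  noise <- withStream(s, rnorm(3100))
  tr <- MotionTrace(noise, frame_rate_hz = 30, stim_onset_frame = 3001,
                    normalized = TRUE)
  th <- whiskingThreshold(tr, pre_window_s = 100)
  expect_equal(th, 3, tolerance = 0.15)

  doubled <- MotionTrace(2 * noise, frame_rate_hz = 30,
                         stim_onset_frame = 3001, normalized = TRUE)
  expect_equal(whiskingThreshold(doubled, 100), 2 * th, tolerance = 1e-12)

  raw <- MotionTrace(noise, frame_rate_hz = 30, stim_onset_frame = 3001)
  expect_error(whiskingThreshold(raw, 100), "normalized")
})

test_that("bouts must last at least half a second", {
  rate <- 30
  mk <- function(runs) {  # runs: c(n_low, n_high, n_low, ...)
    v <- numeric(0)
    high <- FALSE
    for (n in runs) {
      v <- c(v, rep(if (high) 10 else 0, n))
      high <- !high
    }
    v
  }
  no <- detectBouts(mk(c(30, 12, 30)), 1, frame_rate_hz = rate)  # 0.4 s run
  expect_equal(nrow(bouts(no)), 0)

  one <- detectBouts(mk(c(30, 18, 30)), 1, frame_rate_hz = rate)  # 0.6 s
  expect_equal(nrow(bouts(one)), 1)
  expect_equal(bouts(one)$duration_s, 0.6)
  expect_equal(bouts(one)$start_s, 1)

  # two 0.6 s runs split by a single sub-threshold sample
  two <- detectBouts(mk(c(30, 18, 1, 18, 30)), 1, frame_rate_hz = rate)
  expect_equal(nrow(bouts(two)), 2)
})

test_that("bout detection agrees with a brute-force run-length oracle", {
  set.seed(202)
  for (i in 1:300) {
    v <- randomBumpTrace(n_frames = 200, n_bumps = sample(0:4, 1))
    th <- 3
    got <- bouts(detectBouts(v, th, frame_rate_hz = 30))
    want <- boutOracle(v, th, 30)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$duration_s, want$duration_s)
    if (nrow(got)) expect_true(all(got$duration_s >= 0.5))
  }
})

test_that("percent whisking counts trials with window-overlapping bouts", {
  rate <- 30
  mkTrace <- function(whisk) {
    v <- rnorm(150, 0, 1)  # 5 s at 30 Hz; onset frame 61 (2 s in)
    if (whisk) v[97:114] <- v[97:114] + 20  # 1.2-1.8 s after onset
    MotionTrace(v, frame_rate_hz = rate, stim_onset_frame = 61)
  }
  set.seed(7)
  all_whisk <- replicate(20, mkTrace(TRUE), simplify = FALSE)
  expect_equal(percentWhisking(all_whisk), 100)
  none <- replicate(20, mkTrace(FALSE), simplify = FALSE)
  expect_equal(percentWhisking(none), 0)
  expect_error(percentWhisking(list()), "at least one")

  # binomial recovery at per-trial whisking probability 0.6
  set.seed(8)
  flags <- runif(500) < 0.6
  cohort <- lapply(flags, mkTrace)
  expect_equal(percentWhisking(cohort), 60, tolerance = 5 / 60)
})

test_that("displacement and area follow their closed forms", {
  still <- WhiskerTrack(1:40, rep(3, 40), rep(4, 40), stim_onset_frame = 20)
  da <- displacementArea(still)
  expect_equal(da$displacement, rep(0, 40))
  expect_equal(da$area, 0)

  # constant offset d over a 0.5 s window: area = 0.5 * d
  d <- 4
  y <- c(rep(0, 15), rep(d, 25))
  off <- WhiskerTrack(1:40, rep(10, 40), y, frame_rate_hz = 30,
                      stim_onset_frame = 16)
  da2 <- displacementArea(off, stim_window = c(16, 31))
  expect_equal(da2$area, 0.5 * d)

  # half-period sinusoidal deflection vs analytic integral 2*A*T/pi
  A <- 5; n_win <- 31
  t_rel <- seq(0, 1, length.out = n_win)
  y3 <- c(rep(0, 30), A * sin(pi * t_rel))
  tr3 <- WhiskerTrack(seq_len(30 + n_win), rep(0, 30 + n_win), y3,
                      frame_rate_hz = 30, stim_onset_frame = 31)
  da3 <- displacementArea(tr3, stim_window = c(31, 30 + n_win))
  analytic <- 2 * A * (n_win - 1) / 30 / pi
  expect_equal(da3$area, analytic, tolerance = 0.01)

  expect_error(WhiskerTrack(c(1, 2, 4), 1:3, 1:3), "gaps")
  expect_error(WhiskerTrack(1:3, c(1, NA, 3), 1:3), "gaps")
})

test_that("synthetic video ground truth matches the displacement analysis", {
  defl <- c(rep(0, 40), rep(6, 16), rep(0, 34))
  vid <- synthWhiskerVideo(n_frames = 90, deflection = defl,
                           stim_onset_frame = 41)
  da <- displacementArea(vid$track, stim_window = c(41, 56))
  # the rendered tip moves by exactly the deflection in y
  expect_equal(max(da$displacement), 6)
  expect_equal(da$area, 0.5 * 6, tolerance = 1e-9)
})

test_that("end-to-end: known whisking epochs are recovered as bouts", {
  s <- rngStream(99)
  n <- 120
  defl <- numeric(n)
  epoch <- 61:90  # 1 s of whisking starting 0.5 s after onset frame 46
  defl[epoch] <- 6 * sin(2 * pi * 10 * seq_along(epoch) / 30)
  vid <- synthWhiskerVideo(n_frames = n, deflection = defl,
                           noise_sd = 0.01, stream = s)
  tr <- motionEnergy(vid$frames, stim_onset_frame = 46)
  norm <- normalizeTrace(tr)
  th <- whiskingThreshold(norm)
  b <- bouts(detectBouts(norm, th))
  expect_equal(nrow(b), 1)
  truth <- c((epoch[1] - 1) / 30, epoch[length(epoch)] / 30)
  inter <- min(b$end_s, truth[2]) - max(b$start_s, truth[1])
  union <- max(b$end_s, truth[2]) - min(b$start_s, truth[1])
  expect_gt(inter / union, 0.9)
})
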