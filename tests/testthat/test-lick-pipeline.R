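test_that("debouncing keeps one lick per 100 ms grid period", {
  expect_equal(debounceLicks(c(0, 30, 60, 120)), c(0, 120))  # 2 licks
  expect_identical(debounceLicks(numeric(0)), numeric(0))
  expect_equal(debounceLicks(c(0, 100, 200)), c(0, 100, 200))  # 3 periods
  expect_error(debounceLicks(c(200, 100)), "sorted")

  # brute-force period-assignment oracle on random lick sets
  set.seed(101)
  for (i in 1:25) {
    licks <- sort(runif(40, 0, 2000))
    got <- debounceLicks(licks)
    periods <- floor(licks / 100)
    want <- vapply(unique(periods), function(p) min(licks[periods == p]),
                   numeric(1))
    expect_equal(got, sort(want))
  }
})

test_that("anticipatory rate counts debounced licks in [700, 1000) ms", {
  expect_equal(anticipatoryRate(c(710, 820, 930)), 10)  # 3 / 0.3 s
  expect_equal(anticipatoryRate(numeric(0)), 0)
  expect_equal(anticipatoryRate(650), 0)                # outside the window
  expect_equal(anticipatoryRate(c(999, 1000)), 1 / 0.3) # half-open window
  # never above the quantization ceiling, whatever the input
  expect_lte(anticipatoryRate(seq(700, 999, by = 10)), 10)
})

test_that("alignment re-expresses licks relative to the puff onset", {
  trials <- data.frame(init_time_ms = c(10000, 20000),
                       trial_type = c("stim_reward", "blank"),
                       delay_ms = c(0, 400))
  log <- fixtureLog(trials, lick_times = c(9500, 10700, 21100))
  al <- alignTrials(log)
  expect_equal(al$licks_rel_ms[[1]], 700)   # 10700 relative to onset 10000
  expect_equal(al$licks_rel_ms[[2]], 700)   # 21100 relative to onset 20400
  # the lick at 9500 precedes the first trial and belongs to none
  expect_equal(sum(lengths(al$licks_rel_ms)), 2)
  expect_equal(al$anticipatory_rate_hz, c(10 / 3, 10 / 3))
})

test_that("scoring is invariant to the random delay", {
  rel_pattern <- c(150, 720, 810, 950, 1400)
  mk <- function(delay) {
    trials <- data.frame(init_time_ms = 5000, trial_type = "stim_reward",
                         delay_ms = delay)
    log <- fixtureLog(trials, lick_times = 5000 + delay + rel_pattern)
    alignTrials(log)$anticipatory_rate_hz
  }
  expect_equal(mk(200), mk(800))
  expect_equal(mk(347), 10)  # 3 window licks / 0.3 s
})

test_that("simulate-align round trip recovers absolute lick times", {
  cfg <- SessionConfig(session_duration_hr = 2)
  log <- runSession(cfg, AgentParams(init_rate_per_hr = 60), seed = 12)
  al <- alignTrials(log)
  back <- sort(unlist(Map(`+`, al$licks_rel_ms, al$puff_onset_ms)))
  ev <- events(log)
  logged <- sort(ev$timestamp_ms[ev$event_kind == "lick"])
  # licks before the first trial are unassigned by definition
  logged <- logged[logged >= min(al$init_time_ms)]
  expect_equal(unname(back), logged)
})

test_that("bin summaries compute L_w, L_b and performance per 4-hr bin", {
  hr <- 3.6e6
  aligned <- data.frame(
    trial_type = rep(c("stim_reward", "blank"), each = 6),
    init_time_ms = rep(c(1 * hr, 5 * hr, 9 * hr), 4),
    anticipatory_rate_hz = c(rep(6, 6), rep(2, 6)))
  b <- binSummaries(aligned)
  expect_equal(b$bin_index, 1:3)
  expect_equal(b$performance, rep(4, 3))
  expect_equal(b$performance, b$L_w - b$L_b)
  expect_equal(b$n_stim, rep(2, 3))

  # symmetric rates: performance 0
  aligned$anticipatory_rate_hz <- 3
  expect_equal(binSummaries(aligned)$performance, rep(0, 3))

  # a bin without blank trials carries NA, not zero
  lone <- data.frame(trial_type = "stim_reward", init_time_ms = hr,
                     anticipatory_rate_hz = 0)
  b1 <- binSummaries(lone)
  expect_true(is.na(b1$L_b))
  expect_equal(b1$L_w, 0)  # a zero-lick trial still averages in as 0 Hz
})

test_that("the last-20% criterion selects the final trials in time order", {
  aligned <- data.frame(
    trial_id = 1:100,
    trial_type = rep(c("blank", "stim_reward"), 50),
    init_time_ms = (1:100) * 1e4,
    anticipatory_rate_hz = 1:100)
  res <- lastFractionResult(aligned, animal_id = "a1")
  expect_equal(res$n_last, 20)  # trials 81..100
  expect_equal(res$last_L_w, mean(seq(82, 100, 2)))
  expect_equal(res$last_L_b, mean(seq(81, 99, 2)))
  expect_true(res$learned)

  # shuffled input gives the same answer: selection is by time
  shuffled <- aligned[sample(100), ]
  expect_equal(lastFractionResult(shuffled, animal_id = "a1"), res)

  expect_error(lastFractionResult(aligned[1:4, ]), "at least 5")
})

test_that("participation flags animals that stop initiating", {
  cfg <- SessionConfig(session_duration_hr = 8)
  doomed <- AgentParams(init_rate_per_hr = 60, dropout_hazard = 0.2)
  log <- runSession(cfg, doomed, seed = 21)
  expect_false(participation(log, criterion_window_hr = 4)$participated)

  steady <- runSession(cfg, AgentParams(init_rate_per_hr = 30), seed = 21)
  p <- participation(steady, criterion_window_hr = 4)
  expect_true(p$participated)
  expect_equal(p$trials_per_day, p$n_trials / (8 / 24))
})

test_that("the pipeline is deterministic given a log", {
  cfg <- SessionConfig(session_duration_hr = 2)
  log <- runSession(cfg, AgentParams(init_rate_per_hr = 60), seed = 33)
  a <- analyzeLog(log)
  b <- analyzeLog(log)
  expect_identical(a$bins, b$bins)
  expect_identical(a$result, b$result)
})
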