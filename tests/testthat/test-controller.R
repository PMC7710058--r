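test_that("trial-type assignment matches the configured contingency", {
  s <- rngStream(11)
  cfg <- SessionConfig()
  frac <- mean(sampleTrialType(cfg, s, 1e4) == "stim_reward")
  expect_lt(abs(frac - 0.8), 0.01)

  frac50 <- mean(sampleTrialType(SessionConfig(reward_probability = 0.5),
                                 s, 1e4) == "stim_reward")
  expect_lt(abs(frac50 - 0.5), 0.015)

  expect_true(all(sampleTrialType(SessionConfig(reward_probability = 1),
                                  s, 200) == "stim_reward"))
  disc <- sampleTrialType(SessionConfig(mode = "discrimination",
                                        reward_probability = 0), s, 10)
  expect_true(all(disc == "unrewarded_direction"))
})

test_that("random delays are uniform on the configured bounds", {
  s <- rngStream(2)
  cfg <- SessionConfig()
  d <- sampleDelay(cfg, s, 1e4)
  expect_true(all(d >= 200 & d <= 800))
  expect_lt(abs(mean(d) - 500), 5)
  expect_identical(sampleDelay(SessionConfig(delay_min_ms = 500,
                                             delay_max_ms = 500), s, 5),
                   rep(500, 5))
})

test_that("dispensed volume follows the 0.2 uL/ms calibration", {
  cfg <- SessionConfig()
  expect_equal(dispensedVolume(cfg, 1), 15)
  expect_equal(dispensedVolume(cfg, 0), 0)
  vol200 <- dispensedVolume(cfg, 200)
  expect_equal(vol200, 3000)  # 3.0 ml, inside the 1-3 ml/day envelope
  expect_true(vol200 / 1000 >= 1 && vol200 / 1000 <= 3)
  expect_error(dispensedVolume(cfg, -1), "non-negative")
})

test_that("session configs are validated", {
  expect_error(SessionConfig(reward_probability = 1.2), "reward_probability")
  expect_error(SessionConfig(delay_min_ms = 900, delay_max_ms = 800),
               "delay_min_ms")
  expect_error(SessionConfig(puff_duration_ms = 0), "durations")
  expect_error(SessionConfig(session_duration_hr = -1),
               "session_duration_hr")
})

test_that("a silent agent leaves actuation events but no licks in the log", {
  cfg <- SessionConfig(session_duration_hr = 2)
  mute <- AgentParams(baseline_lick_rate_hz = 0, asymptote_hz = 0,
                      consummatory_rate_hz = 0, novelty_suppression = 0,
                      init_rate_per_hr = 60)
  log <- runSession(cfg, mute, seed = 3)
  kinds <- events(log)$event_kind
  expect_true(all(c("nosepoke", "puff_on", "water_on") %in% kinds))
  expect_false("lick" %in% kinds)
})

test_that("simulated sessions honour the actuation schedule exactly", {
  cfg <- SessionConfig(session_duration_hr = 6)
  ag <- AgentParams(init_rate_per_hr = 120)  # stress the lockout
  log <- runSession(cfg, ag, seed = 7)
  expect_true(validObject(log))
  ev <- events(log)
  tr <- trialRecords(log)

  # lockout: consecutive (virtual) puff onsets at least 2 s apart
  expect_gte(min(diff(tr$puff_onset_ms)), 2000)
  # delays within the configured bounds
  expect_true(all(tr$random_delay_ms >= 200 & tr$random_delay_ms <= 800))

  puff_on <- ev[ev$event_kind == "puff_on", ]
  puff_off <- ev[ev$event_kind == "puff_off", ]
  expect_true(all(puff_off$timestamp_ms - puff_on$timestamp_ms == 500))
  w_on <- ev[ev$event_kind == "water_on", ]
  w_off <- ev[ev$event_kind == "water_off", ]
  expect_true(all(w_off$timestamp_ms - w_on$timestamp_ms == 75))
  stim <- tr[tr$trial_type == "stim_reward", ]
  expect_true(all(stim$water_onset_ms - stim$puff_onset_ms == 1000))

  # no event precedes its trial's nosepoke (sensor-grid timestamp)
  first_by_trial <- tapply(ev$timestamp_ms, ev$trial_id, min)
  np <- ev[ev$event_kind == "nosepoke", ]
  expect_true(all(first_by_trial[as.character(np$trial_id)] ==
                    np$timestamp_ms))

  # blank trials: sham relay click, no puff, no water
  blank_ids <- tr$trial_id[tr$trial_type == "blank"]
  blank_ev <- ev[ev$trial_id %in% blank_ids, ]
  expect_true(all(c("relay_click") %in% blank_ev$event_kind))
  expect_false(any(blank_ev$event_kind %in%
                     c("puff_on", "puff_off", "water_on", "water_off")))
})

test_that("replaying a seed reproduces the log exactly", {
  cfg <- SessionConfig(session_duration_hr = 2)
  ag <- AgentParams(init_rate_per_hr = 40)
  a <- runSession(cfg, ag, seed = 42)
  b <- runSession(cfg, ag, seed = 42)
  expect_identical(events(a), events(b))
  c <- runSession(cfg, ag, seed = 43)
  expect_false(identical(events(a), events(c)))
})

test_that("acclimation mode delivers water with no puff", {
  cfg <- SessionConfig(mode = "acclimation", session_duration_hr = 3)
  log <- runSession(cfg, AgentParams(init_rate_per_hr = 60), seed = 5)
  ev <- events(log)
  expect_false(any(ev$event_kind %in% c("puff_on", "puff_off")))
  expect_true("water_on" %in% ev$event_kind)
  tr <- trialRecords(log)  # virtual onsets recoverable from water times
  stim <- tr[tr$trial_type == "stim_reward", ]
  expect_true(all(stim$water_onset_ms - stim$puff_onset_ms == 1000))
})

test_that("discrimination mode puffs but does not reward the other direction", {
  cfg <- SessionConfig(mode = "discrimination", session_duration_hr = 3)
  log <- runSession(cfg, AgentParams(init_rate_per_hr = 60), seed = 5)
  tr <- trialRecords(log)
  expect_setequal(unique(tr$trial_type),
                  c("stim_reward", "unrewarded_direction"))
  un <- tr$trial_id[tr$trial_type == "unrewarded_direction"]
  ev <- events(log)
  un_ev <- ev[ev$trial_id %in% un, ]
  expect_true("puff_on" %in% un_ev$event_kind)
  expect_false("water_on" %in% un_ev$event_kind)
})

test_that("child seeds are 32-bit integers and streams are independent", {
  seeds <- vapply(1:50, function(k) childSeed(123456, k), integer(1))
  expect_true(all(abs(seeds) < 2^31))
  expect_false(anyDuplicated(seeds) > 0)
  s1 <- rngStream(childSeed(9, 1))
  s2 <- rngStream(childSeed(9, 2))
  a <- withStream(s1, runif(5))
  b <- withStream(s2, runif(5))
  expect_false(identical(a, b))
  # interleaving draws from s2 does not perturb s1's margin
  s1b <- rngStream(childSeed(9, 1))
  withStream(s1b, runif(2))
  withStream(s2, runif(100))
  expect_identical(withStream(s1b, runif(3)), a[3:5])
})
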