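# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / brute-force scans) and never call the code paths they check.

# Build an event log directly from a trial table and raw lick times,
# bypassing the simulator, for pipeline tests with hand-chosen geometry.
# trials: data.frame(init_time_ms, trial_type, delay_ms)
fixtureLog <- function(trials, lick_times = numeric(0),
                       cfg = SessionConfig(), animal_id = "fixture") {
  n <- nrow(trials)
  onset <- trials$init_time_ms + trials$delay_ms
  id <- seq_len(n)
  stim <- trials$trial_type == "stim_reward"
  rows <- list(data.frame(
    timestamp_ms = ceiling(trials$init_time_ms / 100) * 100,
    event_kind = "nosepoke", trial_id = id,
    payload = sprintf('{"t_ms":%d}', as.integer(trials$init_time_ms))))
  if (any(stim)) {
    w_on <- onset[stim] + cfg@puff_duration_ms + cfg@puff_to_water_gap_ms
    rows <- c(rows, list(
      data.frame(timestamp_ms = onset[stim], event_kind = "puff_on",
                 trial_id = id[stim], payload = "{}"),
      data.frame(timestamp_ms = onset[stim] + cfg@puff_duration_ms,
                 event_kind = "puff_off", trial_id = id[stim],
                 payload = "{}"),
      data.frame(timestamp_ms = w_on, event_kind = "water_on",
                 trial_id = id[stim], payload = "{}"),
      data.frame(timestamp_ms = w_on + cfg@water_duration_ms,
                 event_kind = "water_off", trial_id = id[stim],
                 payload = "{}")))
  }
  if (any(!stim))
    rows <- c(rows, list(
      data.frame(timestamp_ms = onset[!stim], event_kind = "relay_click",
                 trial_id = id[!stim], payload = "{}")))
  if (length(lick_times))
    rows <- c(rows, list(
      data.frame(timestamp_ms = lick_times, event_kind = "lick",
                 trial_id = NA_integer_, payload = "{}")))
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$timestamp_ms), ]
  rownames(ev) <- NULL
  new("EventLog",
      header = list(schema = "satkit-log/1", animal_id = animal_id,
                    seed = 0, config = configAsList(cfg),
                    conventions = list(sensor_grid_ms = cfg@sensor_period_ms)),
      events = ev)
}

# Brute-force whisking-bout oracle: linear scan for maximal supra-threshold
# runs, then duration filter.
boutOracle <- function(values, threshold, rate_hz, min_duration_s = 0.5) {
  above <- values > threshold
  out <- NULL
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      len <- j - i + 1L
      if (len / rate_hz >= min_duration_s)
        out <- rbind(out, c(start_s = (i - 1L) / rate_hz,
                            end_s = j / rate_hz,
                            duration_s = len / rate_hz))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out))
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0))
  else
    as.data.frame(out)
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (untied absolute differences only), mirroring the standard
# two-sided doubling convention.
signedRankEnumP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  min(1, p)
}

# Frame-difference motion-energy oracle: mean squared intensity change per
# frame (first frame replicated to keep length).
frameDiffEnergy <- function(frames) {
  n <- dim(frames)[3L]
  e <- vapply(2:n, function(t) mean((frames[, , t] - frames[, , t - 1L])^2),
              numeric(1))
  c(e[1L], e)
}

# Random normalized-style motion trace with known supra-threshold bumps:
# baseline standard-normal-ish noise plus rectangular excursions of random
# duration. Returns the trace and its frame rate.
randomBumpTrace <- function(n_frames = 300, rate_hz = 30, n_bumps = 3,
                            amp = 10) {
  v <- rnorm(n_frames, 0, 1)
  for (b in seq_len(n_bumps)) {
    len <- sample(3:45, 1)  # 0.1 s to 1.5 s at 30 Hz
    at <- sample(seq_len(n_frames - len), 1)
    v[at:(at + len - 1L)] <- v[at:(at + len - 1L)] + amp
  }
  v
}
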