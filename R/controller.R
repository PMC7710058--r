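## Discrete-event simulator of the homecage trial controller. The controller
## accepts self-initiated nosepokes subject to the lockout, assigns trial
## types i.i.d. Bernoulli, samples the random pre-stimulus delay, schedules
## the actuation events at exact millisecond times, and logs sensor events on
## the 100 ms polling grid.

#' Sample trial types
#'
#' Each initiated trial is independently assigned stimulus+reward with
#' probability \code{reward_probability}; otherwise it is a blank trial
#' (detection and acclimation modes) or an unrewarded-direction puff trial
#' (discrimination mode). Assignment is i.i.d. per trial — the controller
#' uses no balancing blocks.
#'
#' @param cfg [SessionConfig-class].
#' @param stream An [rngStream()].
#' @param n Number of trials to assign.
#' @return Character vector of \code{"stim_reward"} and \code{"blank"} /
#'   \code{"unrewarded_direction"}.
#' @examples
#' s <- rngStream(1)
#' mean(sampleTrialType(SessionConfig(), s, 1e4) == "stim_reward")  # ~0.80
#' @export
sampleTrialType <- function(cfg, stream, n = 1L) {
  stopifnot(is(cfg, "SessionConfig"))
  validObject(cfg)
  other <- if (cfg@mode == "discrimination") "unrewarded_direction" else
    "blank"
  draws <- withStream(stream, runif(n))
  ifelse(draws < cfg@reward_probability, "stim_reward", other)
}

#' Sample random pre-stimulus delays
#'
#' Uniform on the closed integer-millisecond range
#' \code{[delay_min_ms, delay_max_ms]}. The delay decouples the stimulus from
#' the operant cue of the nosepoke.
#'
#' @inheritParams sampleTrialType
#' @return Numeric vector of delays (ms).
#' @export
sampleDelay <- function(cfg, stream, n = 1L) {
  stopifnot(is(cfg, "SessionConfig"))
  if (cfg@delay_min_ms > cfg@delay_max_ms)
    stop("delay_min_ms must be <= delay_max_ms")
  lo <- round(cfg@delay_min_ms)
  hi <- round(cfg@delay_max_ms)
  if (lo == hi) return(rep(lo, n))
  withStream(stream, sample(seq(lo, hi), n, replace = TRUE))
}

#' Water volume dispensed over rewarded trials
#'
#' @param cfg [SessionConfig-class]; the calibration is
#'   \code{dispense_rate_ul_per_ms} (default 0.2, i.e. 15 uL per 75 ms
#'   opening).
#' @param n_rewarded_trials Number of rewarded trials (>= 0).
#' @return Volume in microliters.
#' @examples
#' dispensedVolume(SessionConfig(), 1)    # 15 uL
#' dispensedVolume(SessionConfig(), 200)  # 3000 uL = 3.0 ml
#' @export
dispensedVolume <- function(cfg, n_rewarded_trials) {
  stopifnot(is(cfg, "SessionConfig"))
  if (length(n_rewarded_trials) != 1L || is.na(n_rewarded_trials) ||
      n_rewarded_trials < 0)
    stop("n_rewarded_trials must be a single non-negative count")
  n_rewarded_trials * cfg@water_duration_ms * cfg@dispense_rate_ul_per_ms
}

#' Simulate a full training session
#'
#' Runs the event loop: the agent proposes nosepoke times; the controller
#' accepts a nosepoke as a trial only once the lockout since the previous
#' (virtual) puff onset has elapsed and any post-water break is over; it then
#' assigns the trial type, samples the random delay, and schedules the
#' actuation events. Stimulus trials emit \code{puff_on}/\code{puff_off} and
#' (if rewarded) \code{water_on}/\code{water_off}; blank trials emit a sham
#' \code{relay_click} at the \emph{virtual} puff-onset time (nose-in + delay)
#' so that auditory relay cues are matched while nothing is delivered. In
#' acclimation mode water is scheduled with probability
#' \code{reward_probability} and no puff is ever delivered.
#'
#' The agent's lick stream is generated per trial (baseline before the
#' stimulus, anticipatory rate between stimulus onset and water time on
#' detected rewarded-direction stimulus trials, consummatory rate after
#' water) and merged into the log quantized to the sensor polling grid, as
#' are nosepoke timestamps; actuation events are logged at exact
#' milliseconds. One root seed drives independent child streams for trial
#' type, delay, initiation and within-trial agent behavior, so replaying a
#' seed reproduces the log exactly.
#'
#' @param cfg [SessionConfig-class].
#' @param agent [AgentParams-class].
#' @param seed Integer root seed for the session.
#' @param animal_id Identifier recorded in the log header.
#' @return An [EventLog-class].
#' @examples
#' cfg <- SessionConfig(session_duration_hr = 2)
#' log <- runSession(cfg, AgentParams(init_rate_per_hr = 40), seed = 1)
#' log
#' @export
runSession <- function(cfg, agent, seed, animal_id = "sim") {
  stopifnot(is(cfg, "SessionConfig"), is(agent, "AgentParams"))
  validObject(cfg); validObject(agent)
  if (cfg@session_duration_hr <= 0) stop("session duration must be > 0")

  type_stream <- rngStream(childSeed(seed, 1))
  delay_stream <- rngStream(childSeed(seed, 2))
  init_stream <- rngStream(childSeed(seed, 3))
  agent_stream <- rngStream(childSeed(seed, 4))

  cand <- initiationTimes(agent, cfg, init_stream)
  water_lat <- cfg@puff_duration_ms + cfg@puff_to_water_gap_ms
  trial_span <- water_lat + cfg@water_duration_ms + cfg@post_water_break_ms
  lockout <- cfg@lockout_from_puff_onset_ms
  sensor <- cfg@sensor_period_ms

  n_cap <- length(cand)
  init <- numeric(n_cap); onset <- numeric(n_cap); delays <- numeric(n_cap)
  type <- character(n_cap); water_on <- rep(NA_real_, n_cap)
  detected <- logical(n_cap); lick_list <- vector("list", n_cap)

  strength <- 0; trials <- 0; active <- TRUE
  next_allowed <- 0; k <- 0L
  base_hz <- agent@baseline_lick_rate_hz

  for (t in cand) {
    if (!active) break
    if (t < next_allowed) next
    k <- k + 1L
    tt <- sampleTrialType(cfg, type_stream)
    d <- sampleDelay(cfg, delay_stream)
    on <- t + d
    puffed <- tt != "blank" && cfg@mode != "acclimation"
    rewarded <- tt == "stim_reward"
    w_on <- if (rewarded) on + water_lat else NA_real_
    draw <- withStream(agent_stream, {
      det <- puffed && runif(1) < agent@detection_prob
      ant_hz <- base_hz
      if (det && rewarded) {
        # learned anticipation is expressed only on detected rewarded-
        # direction stimuli; undetected puffs are behaviorally blank
        learned <- base_hz + strength * (agent@asymptote_hz - base_hz)
        nov <- if (agent@novelty_decay_trials > 0)
          exp(-trials / agent@novelty_decay_trials) else
            as.numeric(trials == 0)
        ant_hz <- learned * (1 - agent@novelty_suppression * nov)
      }
      licks <- if (rewarded) {
        .poissonSegments(c(t, on, w_on), c(on, w_on, on + trial_span),
                         c(base_hz, ant_hz, agent@consummatory_rate_hz))
      } else {
        .poissonSegments(c(t, on, on + water_lat),
                         c(on, on + water_lat, on + trial_span),
                         c(base_hz, ant_hz, base_hz))
      }
      drop <- agent@dropout_hazard > 0 && runif(1) < agent@dropout_hazard
      list(det = det, licks = licks, drop = drop)
    })
    lick_list[[k]] <- unique(ceiling(draw$licks / sensor) * sensor)
    init[k] <- t; onset[k] <- on; delays[k] <- d; type[k] <- tt
    water_on[k] <- w_on; detected[k] <- draw$det

    if (draw$det && rewarded) strength <- strength + agent@learning_rate *
        (1 - strength)
    trials <- trials + 1
    if (draw$drop) active <- FALSE
    next_allowed <- max(on + lockout,
                        if (rewarded) w_on + cfg@water_duration_ms +
                          cfg@post_water_break_ms else -Inf)
  }

  idx <- seq_len(k)
  trial_tab <- data.frame(
    trial_id = idx,
    init_time_ms = init[idx],
    trial_type = type[idx],
    random_delay_ms = delays[idx],
    puff_onset_ms = onset[idx],
    water_onset_ms = water_on[idx],
    detected = detected[idx],
    stringsAsFactors = FALSE)

  .assembleLog(cfg, trial_tab, lick_list[idx], seed, animal_id)
}

## Build the EventLog data.frame from the per-trial schedule.
.assembleLog <- function(cfg, tr, lick_list, seed, animal_id) {
  sensor <- cfg@sensor_period_ms
  puffed <- tr$trial_type != "blank" & cfg@mode != "acclimation"
  rewarded <- tr$trial_type == "stim_reward"
  dir_deg <- ifelse(tr$trial_type == "stim_reward",
                    cfg@rewarded_direction_deg, cfg@unrewarded_direction_deg)

  rows <- list(
    data.frame(timestamp_ms = ceiling(tr$init_time_ms / sensor) * sensor,
               event_kind = "nosepoke", trial_id = tr$trial_id,
               payload = sprintf('{"t_ms":%d}',
                                 as.integer(tr$init_time_ms))),
    if (any(puffed)) {
      pay <- if (cfg@mode == "discrimination")
        sprintf('{"direction_deg":%g}', dir_deg[puffed]) else "{}"
      rbind(
        data.frame(timestamp_ms = tr$puff_onset_ms[puffed],
                   event_kind = "puff_on", trial_id = tr$trial_id[puffed],
                   payload = pay),
        data.frame(timestamp_ms = tr$puff_onset_ms[puffed] +
                     cfg@puff_duration_ms,
                   event_kind = "puff_off", trial_id = tr$trial_id[puffed],
                   payload = "{}"))
    },
    {
      bl <- tr$trial_type == "blank"
      if (any(bl))
        data.frame(timestamp_ms = tr$puff_onset_ms[bl],
                   event_kind = "relay_click", trial_id = tr$trial_id[bl],
                   payload = "{}")
    },
    if (any(rewarded)) {
      rbind(
        data.frame(timestamp_ms = tr$water_onset_ms[rewarded],
                   event_kind = "water_on", trial_id = tr$trial_id[rewarded],
                   payload = "{}"),
        data.frame(timestamp_ms = tr$water_onset_ms[rewarded] +
                     cfg@water_duration_ms,
                   event_kind = "water_off",
                   trial_id = tr$trial_id[rewarded], payload = "{}"))
    },
    {
      n_licks <- lengths(lick_list)
      if (sum(n_licks)) {
        data.frame(timestamp_ms = unlist(lick_list),
                   event_kind = "lick",
                   trial_id = rep(tr$trial_id, n_licks), payload = "{}")
      }
    }
  )
  ev <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(ev))
    ev <- data.frame(timestamp_ms = numeric(0), event_kind = character(0),
                     trial_id = integer(0), payload = character(0))
  ord <- order(ev$timestamp_ms,
               match(ev$event_kind, .EVENT_KINDS), ev$trial_id)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL

  header <- list(
    schema = "satkit-log/1",
    animal_id = animal_id,
    seed = as.integer(seed),
    config = configAsList(cfg),
    conventions = list(
      blank_virtual_onset = TRUE,
      nosepoke_payload_exact_ms = TRUE,
      sensor_grid_ms = sensor,
      last_fraction_over_full_training = TRUE))
  new("EventLog", header = header, events = ev)
}

#' Flatten a SessionConfig to a named list
#'
#' Used for log-header snapshots and for round-tripping configurations
#' through the flat key-value config files of the command-line runner.
#'
#' @param cfg [SessionConfig-class].
#' @return Named list of slot values.
#' @export
configAsList <- function(cfg) {
  nm <- slotNames("SessionConfig")
  setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

#' Rebuild a SessionConfig from a named list
#'
#' @param x Named list (e.g. a log-header \code{config} snapshot).
#' @return A [SessionConfig-class].
#' @export
configFromList <- function(x) {
  do.call(SessionConfig, x[names(x) %in% names(formals(SessionConfig))])
}

#' Per-trial records derived from an event log
#'
#' Segments the event stream into trials: the initiation time comes from the
#' nosepoke record (exact milliseconds are carried in the payload; the
#' timestamp itself sits on the sensor grid), the (virtual) puff onset from
#' the \code{puff_on} or sham \code{relay_click} event, and the water onset
#' from \code{water_on} when present. Trial types are inferred from which
#' actuation events occurred.
#'
#' @param log [EventLog-class].
#' @return \code{data.frame} with columns \code{trial_id},
#'   \code{init_time_ms}, \code{trial_type}, \code{random_delay_ms},
#'   \code{puff_onset_ms}, \code{water_onset_ms}.
#' @export
trialRecords <- function(log) {
  stopifnot(is(log, "EventLog"))
  ev <- log@events
  np <- ev[ev$event_kind == "nosepoke", ]
  if (!nrow(np))
    return(data.frame(trial_id = integer(0), init_time_ms = numeric(0),
                      trial_type = character(0),
                      random_delay_ms = numeric(0),
                      puff_onset_ms = numeric(0),
                      water_onset_ms = numeric(0)))
  exact <- vapply(np$payload, function(p) {
    v <- tryCatch(jsonlite::fromJSON(p)$t_ms, error = function(e) NULL)
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  init <- ifelse(is.na(exact), np$timestamp_ms, exact)

  onset_ev <- ev[ev$event_kind %in% c("puff_on", "relay_click"), ]
  onset <- setNames(onset_ev$timestamp_ms, onset_ev$trial_id)
  water_ev <- ev[ev$event_kind == "water_on", ]
  water <- setNames(water_ev$timestamp_ms, water_ev$trial_id)

  id <- np$trial_id
  on <- unname(onset[as.character(id)])
  w <- unname(water[as.character(id)])
  cfg_snap <- log@header$config
  mode <- cfg_snap$mode %||% "detection"
  if (identical(mode, "acclimation") && any(is.na(on))) {
    water_lat <- (cfg_snap$puff_duration_ms %||% 500) +
      (cfg_snap$puff_to_water_gap_ms %||% 500)
    on[is.na(on)] <- ifelse(is.na(w[is.na(on)]), NA_real_,
                            w[is.na(on)] - water_lat)
  }
  if (anyNA(on))
    stop("trial(s) without a (virtual) puff onset: ",
         paste(id[is.na(on)], collapse = ", "))
  has_puff <- id %in% ev$trial_id[ev$event_kind == "puff_on"]
  tt <- ifelse(!is.na(w), "stim_reward",
               ifelse(has_puff, "unrewarded_direction", "blank"))
  data.frame(trial_id = id, init_time_ms = init, trial_type = tt,
             random_delay_ms = on - init, puff_onset_ms = on,
             water_onset_ms = w, stringsAsFactors = FALSE)
}
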