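## The synthetic mouse. The agent produces nosepoke candidate times and
## Poisson lick streams whose statistics carry the learning structure seen in
## homecage sensory association training: a stimulus-trial anticipatory rate
## that rises with rewarded, detected pairings, blank-trial licking pinned at
## baseline, novelty suppression at training onset, intensity-dependent
## detection, and dropout at aversive intensities.

#' Expected anticipatory lick rate of the agent
#'
#' On stimulus trials the rate interpolates between baseline and the learned
#' asymptote according to the current association strength, multiplied by a
#' novelty-suppression factor \code{1 - s0 * exp(-trials / tau)} that starts
#' below 1 and decays toward 1 with experience — so an early-training agent
#' licks \emph{less} on stimulus trials than on blanks (the habituation dip).
#' Blank trials always return baseline.
#'
#' @param params [AgentParams-class].
#' @param state [AgentState-class].
#' @param trial_type \code{"stim_reward"}, \code{"blank"} or
#'   \code{"unrewarded_direction"}.
#' @return Expected lick rate in Hz.
#' @examples
#' p <- AgentParams(novelty_suppression = 0.5)
#' agentLickRate(p, AgentState(), "stim_reward")   # suppressed below baseline
#' agentLickRate(p, AgentState(), "blank")         # baseline
#' @export
agentLickRate <- function(params, state, trial_type) {
  stopifnot(is(params, "AgentParams"), is(state, "AgentState"))
  base <- params@baseline_lick_rate_hz
  if (trial_type != "stim_reward") return(base)
  learned <- base + state@association_strength * (params@asymptote_hz - base)
  decay <- if (params@novelty_decay_trials > 0) {
    exp(-state@trials_experienced / params@novelty_decay_trials)
  } else {
    as.numeric(state@trials_experienced == 0)
  }
  learned * (1 - params@novelty_suppression * decay)
}

#' Advance the agent's learning state by one trial
#'
#' The association strength follows an exponential-approach update: a
#' detected \emph{and} rewarded pairing moves it a fraction
#' \code{learning_rate} of the remaining distance toward 1, so after k such
#' pairings the strength is \code{1 - (1 - learning_rate)^k}. Trials
#' experienced always increment. Dropout is sampled once per trial with
#' probability \code{dropout_hazard}; once inactive the agent never initiates
#' again.
#'
#' @param params [AgentParams-class].
#' @param state [AgentState-class].
#' @param detected,rewarded Logical outcome of the trial.
#' @param stream Optional [rngStream()] used for the dropout draw; with
#'   \code{NULL} no dropout is sampled (useful for deterministic updates).
#' @return The new [AgentState-class].
#' @examples
#' s <- AgentState()
#' s <- updateAgentState(AgentParams(learning_rate = 0.01), s, TRUE, TRUE)
#' s@association_strength  # 0.01
#' @export
updateAgentState <- function(params, state, detected, rewarded,
                             stream = NULL) {
  stopifnot(is(params, "AgentParams"), is(state, "AgentState"))
  strength <- state@association_strength
  if (isTRUE(detected) && isTRUE(rewarded))
    strength <- strength + params@learning_rate * (1 - strength)
  active <- state@active
  if (!is.null(stream) && params@dropout_hazard > 0 &&
      withStream(stream, runif(1)) < params@dropout_hazard)
    active <- FALSE
  new("AgentState", association_strength = strength,
      trials_experienced = state@trials_experienced + 1, active = active)
}

#' Generate a Poisson lick stream over a trial
#'
#' Licks are emitted as an inhomogeneous Poisson process with a
#' piecewise-constant rate profile (baseline before the stimulus,
#' anticipatory rate from stimulus onset to water onset, consummatory rate
#' after water), then quantized to the lick-sensor polling grid: a lick is
#' recorded at the polling update that follows it, and the sensor updates
#' every \code{sensor_period_ms}, so at most one lick is recorded per grid
#' period regardless of the true lick rate.
#'
#' @param profile \code{data.frame} with columns \code{start_ms},
#'   \code{end_ms}, \code{rate_hz} (disjoint half-open segments, rates >= 0).
#' @param stream An [rngStream()].
#' @param sensor_period_ms Polling period of the sensor grid (ms); use
#'   \code{NULL} to return unquantized event times.
#' @return Sorted numeric vector of lick timestamps (ms).
#' @examples
#' s <- rngStream(7)
#' prof <- data.frame(start_ms = 0, end_ms = 1000, rate_hz = 30)
#' licks <- generateLicks(prof, s)
#' all(diff(licks) >= 100)  # sensor cap: one lick per 100 ms period
#' @export
generateLicks <- function(profile, stream, sensor_period_ms = 100) {
  stopifnot(is.data.frame(profile),
            all(c("start_ms", "end_ms", "rate_hz") %in% names(profile)))
  if (any(profile$rate_hz < 0)) stop("lick rates must be >= 0")
  times <- withStream(
    stream, .poissonSegments(profile$start_ms, profile$end_ms,
                             profile$rate_hz))
  if (!is.null(sensor_period_ms))
    times <- unique(ceiling(times / sensor_period_ms) * sensor_period_ms)
  times
}

## Vector core of the inhomogeneous Poisson sampler; caller owns the RNG
## state. One rpois over all segments, then uniform placement per segment.
.poissonSegments <- function(start_ms, end_ms, rate_hz) {
  len_ms <- pmax(end_ms - start_ms, 0)
  n <- rpois(length(start_ms), rate_hz * len_ms / 1000)
  tot <- sum(n)
  if (tot == 0L) return(numeric(0))
  lo <- rep(start_ms, n)
  hi <- rep(end_ms, n)
  sort(lo + runif(tot) * (hi - lo))
}

#' Generate diurnally modulated nosepoke candidate times
#'
#' Trial initiations follow an inhomogeneous Poisson process whose rate is
#' sinusoidally modulated over 24 h, peaking in the middle of the dark phase
#' (1:00, for lights on 7:00-19:00), as homecage mice initiate most trials at
#' night. These are candidates: the controller enforces the lockout and a
#' dropout agent is truncated by the session loop.
#'
#' @param params [AgentParams-class].
#' @param cfg [SessionConfig-class] (session duration and clock origin).
#' @param stream An [rngStream()].
#' @return Sorted numeric vector of candidate nosepoke times (ms since
#'   session start).
#' @export
initiationTimes <- function(params, cfg, stream) {
  stopifnot(is(params, "AgentParams"), is(cfg, "SessionConfig"))
  dur_hr <- cfg@session_duration_hr
  base_hr <- params@init_rate_per_hr
  amp <- params@diurnal_amplitude
  if (base_hr == 0) return(numeric(0))
  peak_clock <- 1  # middle of the dark phase (19:00-07:00)
  rate_at <- function(t_hr) {
    clock <- (cfg@training_onset_clock + t_hr) %% 24
    base_hr * (1 + amp * cos(2 * pi * (clock - peak_clock) / 24))
  }
  lambda_max <- base_hr * (1 + amp)
  withStream(stream, {
    n <- rpois(1L, lambda_max * dur_hr)
    cand <- sort(runif(n, 0, dur_hr))
    keep <- runif(n) < rate_at(cand) / lambda_max
    round(cand[keep] * 3.6e6)
  })
}
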