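#' @import methods
#' @importFrom stats runif rpois rnorm quantile sd median setNames
NULL

## ---------------------------------------------------------------------------
## SessionConfig
## ---------------------------------------------------------------------------

#' Trial-controller session configuration
#'
#' Holds every timing and contingency parameter of the homecage trial
#' controller: the probability that an initiated trial is a stimulus+reward
#' trial, the random pre-stimulus delay bounds, actuation durations, the
#' lockout from air-puff onset, the sensor polling period, and the water
#' calibration. The paradigm is thereby represented as data: a 48-h detection
#' session at 6 psi and a reduced-contingency (50/50) session differ only in
#' their \code{SessionConfig}.
#'
#' @slot reward_probability Probability in [0, 1] that an initiated trial is
#'   a stimulus+reward trial (0.8 standard; 0.5 reduced contingency).
#' @slot mode One of \code{"acclimation"}, \code{"detection"},
#'   \code{"discrimination"}. Acclimation delivers water with no air puff;
#'   discrimination replaces blank trials by unrewarded-direction puff trials.
#' @slot delay_min_ms,delay_max_ms Bounds (ms) of the uniform random delay
#'   between nosepoke and stimulus onset.
#' @slot puff_duration_ms Solenoid opening time for the air puff (ms).
#' @slot puff_to_water_gap_ms Gap between puff offset and water onset (ms).
#' @slot water_duration_ms Water valve opening time (ms).
#' @slot post_water_break_ms Break after water offset during which no trial
#'   can be initiated (ms).
#' @slot lockout_from_puff_onset_ms Minimum interval between consecutive
#'   (virtual) puff onsets (ms).
#' @slot sensor_period_ms Lick/IR-beam polling period (ms); sensor events are
#'   quantized to this grid.
#' @slot dispense_rate_ul_per_ms Water calibration (microliters per ms of
#'   valve opening); default 0.2 so that 75 ms delivers 15 uL.
#' @slot stimulus_intensity_psi Air-puff intensity label (psi). Affects the
#'   agent's detection and dropout, never the controller schedule.
#' @slot rewarded_direction_deg,unrewarded_direction_deg Puff directions
#'   (degrees), used in discrimination mode only.
#' @slot session_duration_hr Session length in hours.
#' @slot training_onset_clock Clock time (fractional hours, 0-24) at which
#'   the session starts; default 12 (noon, daylight period).
#'
#' @seealso [SessionConfig()] for the user constructor, [runSession()].
#' @export
setClass("SessionConfig",
  representation(
    reward_probability = "numeric",
    mode = "character",
    delay_min_ms = "numeric",
    delay_max_ms = "numeric",
    puff_duration_ms = "numeric",
    puff_to_water_gap_ms = "numeric",
    water_duration_ms = "numeric",
    post_water_break_ms = "numeric",
    lockout_from_puff_onset_ms = "numeric",
    sensor_period_ms = "numeric",
    dispense_rate_ul_per_ms = "numeric",
    stimulus_intensity_psi = "numeric",
    rewarded_direction_deg = "numeric",
    unrewarded_direction_deg = "numeric",
    session_duration_hr = "numeric",
    training_onset_clock = "numeric"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  p <- object@reward_probability
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    msg <- c(msg, "reward_probability must be a single value in [0, 1]")
  if (!object@mode %in% c("acclimation", "detection", "discrimination"))
    msg <- c(msg, "mode must be 'acclimation', 'detection' or 'discrimination'")
  if (object@delay_min_ms > object@delay_max_ms)
    msg <- c(msg, "delay_min_ms must be <= delay_max_ms")
  if (object@delay_min_ms < 0)
    msg <- c(msg, "delays must be non-negative")
  durs <- c(puff_duration_ms = object@puff_duration_ms,
            puff_to_water_gap_ms = object@puff_to_water_gap_ms,
            water_duration_ms = object@water_duration_ms,
            post_water_break_ms = object@post_water_break_ms,
            lockout_from_puff_onset_ms = object@lockout_from_puff_onset_ms,
            sensor_period_ms = object@sensor_period_ms)
  if (any(durs <= 0))
    msg <- c(msg, paste("all durations must be > 0; offending:",
                        paste(names(durs)[durs <= 0], collapse = ", ")))
  if (object@dispense_rate_ul_per_ms <= 0)
    msg <- c(msg, "dispense_rate_ul_per_ms must be > 0")
  if (object@session_duration_hr <= 0)
    msg <- c(msg, "session_duration_hr must be > 0")
  if (object@training_onset_clock < 0 || object@training_onset_clock >= 24)
    msg <- c(msg, "training_onset_clock must be in [0, 24)")
  if (length(msg)) msg else TRUE
})

#' Construct a session configuration
#'
#' Defaults reproduce the standard detection-mode training session: trials
#' self-initiated at a nosepoke, a uniform 200-800 ms delay, a 500 ms air
#' puff, a 500 ms gap, 75 ms of water (~15 uL at the default calibration), a
#' 925 ms post-water break, a 2 s lockout from puff onset, and stimulus+reward
#' on 80% of initiated trials.
#'
#' Note the 2 s lockout equals puff + gap + water + break
#' (500 + 500 + 75 + 925 ms) for rewarded trials; the controller enforces the
#' maximum of the two constraints, so neither needs to dominate.
#'
#' @param reward_probability,mode,delay_min_ms,delay_max_ms See slots.
#' @param puff_duration_ms,puff_to_water_gap_ms,water_duration_ms See slots.
#' @param post_water_break_ms,lockout_from_puff_onset_ms See slots.
#' @param sensor_period_ms,dispense_rate_ul_per_ms See slots.
#' @param stimulus_intensity_psi,rewarded_direction_deg See slots.
#' @param unrewarded_direction_deg,session_duration_hr See slots.
#' @param training_onset_clock See slots.
#' @return A validated [SessionConfig-class] object.
#' @examples
#' cfg <- SessionConfig()
#' cfg50 <- SessionConfig(reward_probability = 0.5)
#' @export
SessionConfig <- function(reward_probability = 0.8,
                          mode = c("detection", "acclimation",
                                   "discrimination"),
                          delay_min_ms = 200,
                          delay_max_ms = 800,
                          puff_duration_ms = 500,
                          puff_to_water_gap_ms = 500,
                          water_duration_ms = 75,
                          post_water_break_ms = 925,
                          lockout_from_puff_onset_ms = 2000,
                          sensor_period_ms = 100,
                          dispense_rate_ul_per_ms = 0.2,
                          stimulus_intensity_psi = 6,
                          rewarded_direction_deg = 0,
                          unrewarded_direction_deg = 180,
                          session_duration_hr = 48,
                          training_onset_clock = 12) {
  mode <- match.arg(mode)
  new("SessionConfig",
      reward_probability = reward_probability,
      mode = mode,
      delay_min_ms = delay_min_ms,
      delay_max_ms = delay_max_ms,
      puff_duration_ms = puff_duration_ms,
      puff_to_water_gap_ms = puff_to_water_gap_ms,
      water_duration_ms = water_duration_ms,
      post_water_break_ms = post_water_break_ms,
      lockout_from_puff_onset_ms = lockout_from_puff_onset_ms,
      sensor_period_ms = sensor_period_ms,
      dispense_rate_ul_per_ms = dispense_rate_ul_per_ms,
      stimulus_intensity_psi = stimulus_intensity_psi,
      rewarded_direction_deg = rewarded_direction_deg,
      unrewarded_direction_deg = unrewarded_direction_deg,
      session_duration_hr = session_duration_hr,
      training_onset_clock = training_onset_clock)
}

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig (", object@mode, " mode)\n", sep = "")
  cat("  stimulus+reward probability:", object@reward_probability, "\n")
  cat("  random delay: [", object@delay_min_ms, ", ", object@delay_max_ms,
      "] ms\n", sep = "")
  cat("  puff ", object@puff_duration_ms, " ms | gap ",
      object@puff_to_water_gap_ms, " ms | water ", object@water_duration_ms,
      " ms | break ", object@post_water_break_ms, " ms\n", sep = "")
  cat("  lockout from puff onset:", object@lockout_from_puff_onset_ms, "ms\n")
  cat("  intensity:", object@stimulus_intensity_psi, "psi | duration:",
      object@session_duration_hr, "hr\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## AgentParams / AgentState
## ---------------------------------------------------------------------------

#' Parameters of the synthetic mouse
#'
#' The agent emulates the behavioral structure observed during sensory
#' association training: Poisson lick streams whose stimulus-trial
#' anticipatory rate rises with training while blank-trial licking stays at
#' baseline, novelty suppression of stimulus-trial licking at training onset,
#' intensity-dependent stimulus detection, dropout at aversive intensities,
#' and diurnally modulated trial initiation.
#'
#' @slot baseline_lick_rate_hz Licking rate (Hz) absent specific anticipation.
#' @slot asymptote_hz Fully-learned anticipatory rate on stimulus trials (Hz).
#' @slot learning_rate Per detected-and-rewarded pairing increment constant of
#'   the exponential-approach associative update.
#' @slot novelty_suppression Fractional suppression of stimulus-trial licking
#'   at training onset (0 = none).
#' @slot novelty_decay_trials Trial constant of the exponential decay of
#'   novelty suppression.
#' @slot consummatory_rate_hz Licking rate after water delivery (Hz).
#' @slot init_rate_per_hr Mean trial-initiation rate (nosepokes/hr).
#' @slot diurnal_amplitude Fractional sinusoidal modulation of the initiation
#'   rate over 24 h (peak in the dark phase).
#' @slot detection_prob Probability that a given air puff is detected;
#'   a function of stimulus intensity, 0 for a barbered (whisker-less) agent.
#' @slot dropout_hazard Per-trial probability of permanent cessation of trial
#'   initiation (elevated at aversive high intensities).
#' @slot whiskered Logical; \code{FALSE} models a barbered animal and forces
#'   \code{detection_prob = 0}.
#'
#' @seealso [AgentParams()], [agentDefaults()], [runSession()].
#' @export
setClass("AgentParams",
  representation(
    baseline_lick_rate_hz = "numeric",
    asymptote_hz = "numeric",
    learning_rate = "numeric",
    novelty_suppression = "numeric",
    novelty_decay_trials = "numeric",
    consummatory_rate_hz = "numeric",
    init_rate_per_hr = "numeric",
    diurnal_amplitude = "numeric",
    detection_prob = "numeric",
    dropout_hazard = "numeric",
    whiskered = "logical"
  )
)

setValidity("AgentParams", function(object) {
  msg <- character()
  rates <- c(baseline = object@baseline_lick_rate_hz,
             asymptote = object@asymptote_hz,
             consummatory = object@consummatory_rate_hz,
             init = object@init_rate_per_hr,
             learning_rate = object@learning_rate,
             novelty_decay = object@novelty_decay_trials)
  if (any(rates < 0))
    msg <- c(msg, "rates and constants must be >= 0")
  probs <- c(novelty_suppression = object@novelty_suppression,
             detection_prob = object@detection_prob,
             dropout_hazard = object@dropout_hazard,
             diurnal_amplitude = object@diurnal_amplitude,
             learning_rate = object@learning_rate)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities/fractions must be in [0, 1]")
  if (!object@whiskered && object@detection_prob != 0)
    msg <- c(msg, "whiskered = FALSE forces detection_prob = 0")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic-mouse parameters
#'
#' @param baseline_lick_rate_hz,asymptote_hz,learning_rate See slots of
#'   [AgentParams-class].
#' @param novelty_suppression,novelty_decay_trials See slots.
#' @param consummatory_rate_hz,init_rate_per_hr,diurnal_amplitude See slots.
#' @param detection_prob,dropout_hazard,whiskered See slots.
#' @return A validated [AgentParams-class] object.
#' @examples
#' learner <- AgentParams()
#' barbered <- AgentParams(whiskered = FALSE, detection_prob = 0)
#' @export
AgentParams <- function(baseline_lick_rate_hz = 2,
                        asymptote_hz = 8,
                        learning_rate = 0.01,
                        novelty_suppression = 0.5,
                        novelty_decay_trials = 50,
                        consummatory_rate_hz = 8,
                        init_rate_per_hr = 20,
                        diurnal_amplitude = 0.5,
                        detection_prob = 0.9,
                        dropout_hazard = 0,
                        whiskered = TRUE) {
  new("AgentParams",
      baseline_lick_rate_hz = baseline_lick_rate_hz,
      asymptote_hz = asymptote_hz,
      learning_rate = learning_rate,
      novelty_suppression = novelty_suppression,
      novelty_decay_trials = novelty_decay_trials,
      consummatory_rate_hz = consummatory_rate_hz,
      init_rate_per_hr = init_rate_per_hr,
      diurnal_amplitude = diurnal_amplitude,
      detection_prob = detection_prob,
      dropout_hazard = dropout_hazard,
      whiskered = whiskered)
}

#' Intensity-specific agent defaults
#'
#' Maps the stimulus-intensity label (psi) to the agent's detection
#' probability and dropout hazard: low intensity (2 psi) is hard to detect
#' but not aversive; medium (6 psi) is reliably detected with no dropout;
#' high (9 psi) is detected slightly better but aversive enough that a
#' substantial fraction of agents stop initiating trials during a multi-day
#' session. These are configuration defaults chosen to reproduce the
#' qualitative intensity ordering, not measured quantities.
#'
#' @param psi Intensity label; one of 2, 6, 9.
#' @param whiskered Logical; \code{FALSE} gives a barbered agent
#'   (\code{detection_prob = 0}).
#' @param ... Further arguments passed to [AgentParams()].
#' @return An [AgentParams-class] object.
#' @examples
#' agentDefaults(9)  # elevated dropout hazard
#' @export
agentDefaults <- function(psi = 6, whiskered = TRUE, ...) {
  psi <- as.character(psi)
  det <- c("2" = 0.4, "6" = 0.9, "9" = 0.95)[psi]
  drop <- c("2" = 0, "6" = 0, "9" = 8e-4)[psi]
  if (is.na(det))
    stop("psi must be one of 2, 6, 9 (configuration labels)")
  if (!whiskered) det <- 0
  AgentParams(detection_prob = unname(det), dropout_hazard = unname(drop),
              whiskered = whiskered, ...)
}

#' Mutable state of the synthetic mouse
#'
#' @slot association_strength Unitless strength of the puff-water association
#'   in [0, 1]; monotone non-decreasing under detected, rewarded pairings.
#' @slot trials_experienced Number of trials experienced so far.
#' @slot active Logical; \code{FALSE} after dropout (the agent never
#'   initiates again).
#' @export
setClass("AgentState",
  representation(association_strength = "numeric",
                 trials_experienced = "numeric",
                 active = "logical")
)

setValidity("AgentState", function(object) {
  msg <- character()
  if (object@association_strength < 0 || object@association_strength > 1)
    msg <- c(msg, "association_strength must be in [0, 1]")
  if (object@trials_experienced < 0)
    msg <- c(msg, "trials_experienced must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a naive agent state
#'
#' @param association_strength,trials_experienced,active Slot values; the
#'   defaults describe a naive, active animal.
#' @return An [AgentState-class] object.
#' @export
AgentState <- function(association_strength = 0, trials_experienced = 0,
                       active = TRUE) {
  new("AgentState", association_strength = association_strength,
      trials_experienced = trials_experienced, active = active)
}

## ---------------------------------------------------------------------------
## EventLog
## ---------------------------------------------------------------------------

.EVENT_KINDS <- c("nosepoke", "puff_on", "puff_off", "water_on", "water_off",
                  "relay_click", "lick")

#' Timestamped session event log
#'
#' The controller's output: an ordered stream of
#' \code{nosepoke}/\code{puff_on}/\code{puff_off}/\code{water_on}/
#' \code{water_off}/\code{relay_click}/\code{lick} records with millisecond
#' timestamps and trial ids, plus a header carrying the
#' configuration snapshot, root seed, animal id and the logging conventions.
#' Blank trials carry a sham \code{relay_click} at the virtual puff-onset
#' time and no puff or water events.
#'
#' @slot header Named list: \code{config} (snapshot of the
#'   [SessionConfig-class]), \code{seed}, \code{animal_id}, \code{schema},
#'   \code{conventions}.
#' @slot events \code{data.frame} with columns \code{timestamp_ms}
#'   (non-decreasing), \code{event_kind}, \code{trial_id}, \code{payload}
#'   (JSON string).
#'
#' @seealso [runSession()], [writeEventLog()], [readEventLog()],
#'   [trialRecords()].
#' @export
setClass("EventLog",
  representation(header = "list", events = "data.frame")
)

setValidity("EventLog", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("timestamp_ms", "event_kind", "trial_id", "payload")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (is.unsorted(ev$timestamp_ms))
      msg <- c(msg, "timestamps must be non-decreasing")
    if (!all(ev$event_kind %in% .EVENT_KINDS))
      msg <- c(msg, "unknown event_kind present")
    dur <- object@header$config
    if (!is.null(dur)) {
      for (pair in list(c("puff_on", "puff_off", "puff_duration_ms"),
                        c("water_on", "water_off", "water_duration_ms"))) {
        on <- ev[ev$event_kind == pair[1L], ]
        off <- ev[ev$event_kind == pair[2L], ]
        if (nrow(on) != nrow(off)) {
          msg <- c(msg, paste("unmatched", pair[1L], "/", pair[2L]))
        } else if (nrow(on) &&
                   !all(off$timestamp_ms - on$timestamp_ms ==
                        dur[[pair[3L]]])) {
          msg <- c(msg, paste(pair[2L], "must follow", pair[1L], "by exactly",
                              dur[[pair[3L]]], "ms"))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for event logs
#'
#' \code{events()} returns the event \code{data.frame}; \code{logHeader()}
#' the header list; \code{nTrials()} the number of initiated trials.
#'
#' @param object An [EventLog-class].
#' @return See description.
#' @rdname EventLog-accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname EventLog-accessors
#' @export
setMethod("events", "EventLog", function(object) object@events)

#' @rdname EventLog-accessors
#' @export
setGeneric("logHeader", function(object) standardGeneric("logHeader"))

#' @rdname EventLog-accessors
#' @export
setMethod("logHeader", "EventLog", function(object) object@header)

#' @rdname EventLog-accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname EventLog-accessors
#' @export
setMethod("nTrials", "EventLog", function(object) {
  ids <- object@events$trial_id
  length(unique(ids[!is.na(ids)]))
})

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat("EventLog:", nrow(ev), "events,", nTrials(object), "trials\n")
  cat("  animal:", object@header$animal_id %||% "<none>",
      "| seed:", object@header$seed %||% NA, "\n")
  if (nrow(ev))
    cat("  span: ", min(ev$timestamp_ms), "-", max(ev$timestamp_ms), " ms\n",
        sep = "")
  kinds <- table(ev$event_kind)
  cat("  ", paste(names(kinds), kinds, sep = ":", collapse = " "), "\n")
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## MotionTrace / BoutSet / WhiskerTrack
## ---------------------------------------------------------------------------

#' Per-frame whisker motion-energy trace
#'
#' @slot values Numeric vector of per-frame motion energy (arbitrary units).
#' @slot frame_rate_hz Video frame rate (Hz), typically ~30.
#' @slot stim_onset_frame 1-based index of the air-puff onset frame.
#' @slot stim_duration_frames Stimulus duration in frames.
#' @slot normalized Logical; \code{TRUE} after baseline subtraction.
#' @seealso [motionEnergy()], [normalizeTrace()], [whiskingThreshold()].
#' @export
setClass("MotionTrace",
  representation(values = "numeric", frame_rate_hz = "numeric",
                 stim_onset_frame = "numeric",
                 stim_duration_frames = "numeric", normalized = "logical")
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (length(object@values) < 2L)
    msg <- c(msg, "a motion trace needs at least 2 frames")
  if (object@frame_rate_hz <= 0)
    msg <- c(msg, "frame_rate_hz must be > 0")
  if (object@stim_onset_frame < 1 ||
      object@stim_onset_frame > length(object@values))
    msg <- c(msg, "stim_onset_frame out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a motion trace
#'
#' @param values,frame_rate_hz,stim_onset_frame,stim_duration_frames,normalized
#'   Slot values; see [MotionTrace-class].
#' @return A [MotionTrace-class] object.
#' @export
MotionTrace <- function(values, frame_rate_hz = 30, stim_onset_frame = 1,
                        stim_duration_frames = 15, normalized = FALSE) {
  new("MotionTrace", values = as.numeric(values),
      frame_rate_hz = frame_rate_hz, stim_onset_frame = stim_onset_frame,
      stim_duration_frames = stim_duration_frames, normalized = normalized)
}

#' @rdname MotionTrace
#' @param object A [MotionTrace-class].
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname MotionTrace
#' @export
setMethod("traceValues", "MotionTrace", function(object) object@values)

#' @rdname MotionTrace
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname MotionTrace
#' @export
setMethod("frameRate", "MotionTrace", function(object) object@frame_rate_hz)

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace: ", length(object@values), " frames @ ",
      object@frame_rate_hz, " Hz",
      if (object@normalized) " (normalized)" else " (raw)", "\n", sep = "")
  cat("  stim onset frame ", object@stim_onset_frame, ", duration ",
      object@stim_duration_frames, " frames\n", sep = "")
  invisible(NULL)
})

#' Set of detected whisking bouts
#'
#' Disjoint, sorted \code{[start_s, end_s]} intervals, each of duration
#' >= the minimum bout duration, together with the threshold used.
#'
#' @slot bouts \code{data.frame} with columns \code{start_s}, \code{end_s},
#'   \code{duration_s}.
#' @slot threshold Whisking threshold the bouts were detected at.
#' @slot min_duration_s Minimum accepted bout duration (s).
#' @seealso [detectBouts()], [percentWhisking()].
#' @export
setClass("BoutSet",
  representation(bouts = "data.frame", threshold = "numeric",
                 min_duration_s = "numeric")
)

setValidity("BoutSet", function(object) {
  b <- object@bouts
  msg <- character()
  if (!all(c("start_s", "end_s", "duration_s") %in% names(b)))
    return("bouts must have columns start_s, end_s, duration_s")
  if (nrow(b)) {
    if (any(b$duration_s < object@min_duration_s - 1e-9))
      msg <- c(msg, "all bouts must last >= min_duration_s")
    if (is.unsorted(b$start_s, strictly = TRUE) && nrow(b) > 1L)
      msg <- c(msg, "bouts must be sorted by start time")
    if (nrow(b) > 1L && any(b$start_s[-1L] < b$end_s[-nrow(b)]))
      msg <- c(msg, "bouts must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname BoutSet-class
#' @param object A [BoutSet-class].
#' @export
setGeneric("bouts", function(object) standardGeneric("bouts"))

#' @rdname BoutSet-class
#' @export
setMethod("bouts", "BoutSet", function(object) object@bouts)

setMethod("show", "BoutSet", function(object) {
  cat("BoutSet:", nrow(object@bouts), "whisking bouts (threshold",
      signif(object@threshold, 4), ", min duration",
      object@min_duration_s, "s)\n")
  invisible(NULL)
})

#' Whisker-tip coordinate track
#'
#' Per-frame (x, y) tip coordinates from which a non-negative displacement
#' trace (Euclidean distance from the pre-stimulus rest position) and a
#' per-trial area under the displacement curve are derived.
#'
#' @slot frame Integer frame indices (1-based, gap-free).
#' @slot x,y Tip coordinates (pixels, or mm if a scale has been applied).
#' @slot frame_rate_hz Frame rate (Hz).
#' @slot stim_onset_frame Air-puff onset frame.
#' @seealso [displacementArea()].
#' @export
setClass("WhiskerTrack",
  representation(frame = "numeric", x = "numeric", y = "numeric",
                 frame_rate_hz = "numeric", stim_onset_frame = "numeric")
)

setValidity("WhiskerTrack", function(object) {
  msg <- character()
  n <- length(object@frame)
  if (length(object@x) != n || length(object@y) != n)
    msg <- c(msg, "frame, x, y must have equal length")
  if (n && any(diff(object@frame) != 1))
    msg <- c(msg, "track has gaps: frames must be consecutive")
  if (anyNA(object@x) || anyNA(object@y))
    msg <- c(msg, "track has gaps: NA coordinates present")
  if (object@frame_rate_hz <= 0)
    msg <- c(msg, "frame_rate_hz must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a whisker-tip track
#'
#' @param frame,x,y,frame_rate_hz,stim_onset_frame Slot values; see
#'   [WhiskerTrack-class].
#' @return A [WhiskerTrack-class] object.
#' @export
WhiskerTrack <- function(frame, x, y, frame_rate_hz = 30,
                         stim_onset_frame = 1) {
  new("WhiskerTrack", frame = as.numeric(frame), x = as.numeric(x),
      y = as.numeric(y), frame_rate_hz = frame_rate_hz,
      stim_onset_frame = stim_onset_frame)
}

setMethod("show", "WhiskerTrack", function(object) {
  cat("WhiskerTrack:", length(object@frame), "frames @",
      object@frame_rate_hz, "Hz, stim onset frame",
      object@stim_onset_frame, "\n")
  invisible(NULL)
})
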