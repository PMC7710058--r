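## Anticipatory-licking analysis. All lick times are re-expressed relative to
## the (virtual) air-puff onset of their trial, debounced on a 100 ms grid
## anchored at that onset, counted in the 700-1000 ms window (the 300 ms
## directly before water delivery), converted to Hz, binned into 4-hour
## intervals, and summarized as performance = L_w - L_b. The pipeline is
## deterministic: given a log it has no internal randomness.

#' Collapse licks onto the sensor counting grid
#'
#' At most one lick is counted per \code{period_ms} grid period; the grid is
#' anchored at time zero of whatever reference the timestamps use (trial
#' alignment anchors it at puff onset, so the anticipatory window spans
#' exactly three periods). Periods are half-open: \code{[k*P, (k+1)*P)}.
#'
#' @param times Sorted numeric lick timestamps (ms).
#' @param period_ms Grid period (default 100 ms).
#' @return Sorted timestamps, at most one per grid period (the first in each
#'   period is kept).
#' @examples
#' debounceLicks(c(0, 30, 60, 120))  # 0, 120 -> two counted licks
#' debounceLicks(c(0, 100, 200))     # three periods, three licks
#' @export
debounceLicks <- function(times, period_ms = 100) {
  if (!length(times)) return(numeric(0))
  if (is.unsorted(times)) stop("lick timestamps must be sorted")
  keep <- !duplicated(floor(times / period_ms))
  times[keep]
}

#' Anticipatory lick rate of one aligned trial
#'
#' Counts debounced licks whose onset-relative time falls in the half-open
#' scoring window (default \code{[700, 1000)} ms after the puff onset, i.e.
#' the 300 ms directly before water delivery) and converts the count to Hz.
#' Trials without licks score 0 Hz and are averaged in like any other trial.
#'
#' @param licks_rel_ms Lick times relative to the (virtual) puff onset (ms);
#'   debounced internally on the onset-anchored grid.
#' @param window Half-open scoring window \code{c(lo, hi)} in ms.
#' @param period_ms Debouncing grid period (ms).
#' @return Rate in Hz (count / window length).
#' @examples
#' anticipatoryRate(c(710, 820, 930))  # 3 licks / 0.3 s = 10 Hz
#' anticipatoryRate(650)               # outside the window: 0 Hz
#' @export
anticipatoryRate <- function(licks_rel_ms, window = c(700, 1000),
                             period_ms = 100) {
  licks <- debounceLicks(sort(licks_rel_ms), period_ms)
  n <- sum(licks >= window[1L] & licks < window[2L])
  n / ((window[2L] - window[1L]) / 1000)
}

#' Align a log's licks to their trials' puff onsets
#'
#' Segments the session into trials and re-expresses every lick relative to
#' its trial's (virtual) puff onset. A lick belongs to the trial whose span
#' \code{[nosepoke, next nosepoke)} contains it; licks before the first trial
#' belong to none. Scoring is thereby invariant to the random delay: trials
#' with identical onset-relative lick patterns score identically whatever
#' their delays.
#'
#' @param log [EventLog-class].
#' @param window Scoring window passed to [anticipatoryRate()].
#' @return \code{data.frame} with one row per trial: \code{trial_id},
#'   \code{trial_type}, \code{init_time_ms}, \code{puff_onset_ms},
#'   \code{licks_rel_ms} (list column), \code{anticipatory_count},
#'   \code{anticipatory_rate_hz}.
#' @export
alignTrials <- function(log, window = c(700, 1000)) {
  stopifnot(is(log, "EventLog"))
  tr <- trialRecords(log)
  period <- log@header$conventions$sensor_grid_ms %||% 100
  ev <- log@events
  licks <- ev$timestamp_ms[ev$event_kind == "lick"]

  n <- nrow(tr)
  rel_list <- rep(list(numeric(0)), n)
  if (n && length(licks)) {
    idx <- findInterval(licks, tr$init_time_ms)
    ok <- idx >= 1L
    rel <- licks[ok] - tr$puff_onset_ms[idx[ok]]
    split_rel <- split(rel, idx[ok])
    rel_list[as.integer(names(split_rel))] <- lapply(split_rel, sort)
  }
  counts <- vapply(rel_list, function(r) {
    d <- debounceLicks(r, period)
    sum(d >= window[1L] & d < window[2L])
  }, numeric(1))
  data.frame(trial_id = tr$trial_id, trial_type = tr$trial_type,
             init_time_ms = tr$init_time_ms,
             puff_onset_ms = tr$puff_onset_ms,
             licks_rel_ms = I(rel_list),
             anticipatory_count = counts,
             anticipatory_rate_hz = counts /
               ((window[2L] - window[1L]) / 1000),
             stringsAsFactors = FALSE)
}

#' Bin anticipatory rates into fixed intervals
#'
#' Computes, per bin anchored at the training onset, the mean anticipatory
#' rate over stimulus trials (\code{L_w}), over blank trials (\code{L_b};
#' during discrimination the unrewarded-direction trials play the blank
#' role), and the performance \code{L_w - L_b}. Zero-lick trials enter the
#' means; a bin with no trials of a type carries \code{NA}, never zero (zero
#' is a meaningful rate).
#'
#' @param aligned Output of [alignTrials()].
#' @param bin_hr Bin width in hours (default 4).
#' @param origin_ms Session time of the training onset (ms; default 0).
#' @return \code{data.frame}: \code{bin_index} (1-based), \code{L_w},
#'   \code{L_b}, \code{performance}, \code{n_stim}, \code{n_blank}.
#' @export
binSummaries <- function(aligned, bin_hr = 4, origin_ms = 0) {
  stopifnot(is.data.frame(aligned), nrow(aligned) > 0)
  bin_ms <- bin_hr * 3.6e6
  bin <- floor((aligned$init_time_ms - origin_ms) / bin_ms) + 1L
  is_stim <- aligned$trial_type == "stim_reward"
  bins <- sort(unique(bin))
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  L_w <- vapply(bins, function(b)
    mean_or_na(aligned$anticipatory_rate_hz[bin == b & is_stim]), numeric(1))
  L_b <- vapply(bins, function(b)
    mean_or_na(aligned$anticipatory_rate_hz[bin == b & !is_stim]),
    numeric(1))
  data.frame(bin_index = bins, L_w = L_w, L_b = L_b,
             performance = L_w - L_b,
             n_stim = vapply(bins, function(b) sum(bin == b & is_stim),
                             numeric(1)),
             n_blank = vapply(bins, function(b) sum(bin == b & !is_stim),
                              numeric(1)))
}

#' Per-animal learning result over the last fraction of trials
#'
#' Selects the final \code{ceiling(fraction * N)} initiated trials of the
#' training phase (all types, in time order), computes \code{L_w} and
#' \code{L_b} over that subset, and flags the animal as having learned when
#' \code{L_w > L_b} there.
#'
#' @param aligned Output of [alignTrials()] for the training phase
#'   (acclimation trials excluded by the caller).
#' @param fraction Fraction of trials to keep from the end (default 0.2).
#' @param animal_id Identifier copied into the result.
#' @return One-row \code{data.frame}: \code{animal_id}, \code{n_trials},
#'   \code{n_last}, \code{last_L_w}, \code{last_L_b}, \code{performance},
#'   \code{learned}.
#' @export
lastFractionResult <- function(aligned, fraction = 0.2, animal_id = NA) {
  stopifnot(is.data.frame(aligned))
  n <- nrow(aligned)
  if (n < 5L)
    stop("need at least 5 trials to score the last-fraction criterion, got ",
         n)
  n_last <- ceiling(fraction * n)
  sub <- aligned[order(aligned$init_time_ms), ][(n - n_last + 1L):n, ]
  is_stim <- sub$trial_type == "stim_reward"
  L_w <- if (any(is_stim)) mean(sub$anticipatory_rate_hz[is_stim]) else
    NA_real_
  L_b <- if (any(!is_stim)) mean(sub$anticipatory_rate_hz[!is_stim]) else
    NA_real_
  data.frame(animal_id = animal_id, n_trials = n, n_last = n_last,
             last_L_w = L_w, last_L_b = L_b, performance = L_w - L_b,
             learned = isTRUE(L_w > L_b), stringsAsFactors = FALSE)
}

#' Participation of an animal across the session
#'
#' An animal participated if it initiated at least one trial during the final
#' \code{criterion_window_hr} hours of the session; animals that stop
#' initiating early (dropout at aversive intensities) fail the criterion.
#' Also reports initiated trials per day.
#'
#' @param log [EventLog-class].
#' @param criterion_window_hr Width of the terminal window (hours).
#' @return List with \code{participated} (logical), \code{trials_per_day}
#'   (numeric), \code{n_trials}.
#' @export
participation <- function(log, criterion_window_hr = 4) {
  stopifnot(is(log, "EventLog"))
  tr <- trialRecords(log)
  dur_hr <- log@header$config$session_duration_hr %||%
    (max(c(0, tr$init_time_ms)) / 3.6e6)
  cut_ms <- (dur_hr - criterion_window_hr) * 3.6e6
  list(participated = any(tr$init_time_ms >= cut_ms),
       trials_per_day = nrow(tr) / (dur_hr / 24),
       n_trials = nrow(tr))
}

#' Full per-animal analysis of one session log
#'
#' Convenience wrapper running alignment, binning, the last-fraction
#' criterion and participation in one call.
#'
#' @param log [EventLog-class].
#' @param bin_hr,fraction,criterion_window_hr Passed through.
#' @return List with elements \code{aligned}, \code{bins}, \code{result}
#'   (one-row \code{data.frame}, including participation), \code{participation}.
#' @export
analyzeLog <- function(log, bin_hr = 4, fraction = 0.2,
                       criterion_window_hr = 4) {
  aligned <- alignTrials(log)
  bins <- binSummaries(aligned, bin_hr = bin_hr)
  res <- lastFractionResult(aligned, fraction = fraction,
                            animal_id = log@header$animal_id %||% NA)
  part <- participation(log, criterion_window_hr)
  res$participated <- part$participated
  res$trials_per_day <- part$trials_per_day
  list(aligned = aligned, bins = bins, result = res, participation = part)
}

#' Simulate and analyze a cohort of synthetic animals
#'
#' Runs one session per animal (seeds derived from the cohort seed) and
#' returns the per-animal results table plus per-animal bin summaries.
#'
#' @param n_animals Number of synthetic animals.
#' @param cfg [SessionConfig-class] shared by the cohort.
#' @param agent [AgentParams-class] shared by the cohort.
#' @param seed Cohort root seed; animal i runs with
#'   \code{childSeed(seed, i)}.
#' @param condition Label recorded per animal (e.g. \code{"6psi"}).
#' @return List with \code{results} (one row per animal: the
#'   [lastFractionResult()] fields plus participation and condition) and
#'   \code{bins} (list of per-animal bin summaries).
#' @examples
#' \donttest{
#' cfg <- SessionConfig(session_duration_hr = 8)
#' coh <- simulateCohort(3, cfg, AgentParams(), seed = 1)
#' coh$results
#' }
#' @export
simulateCohort <- function(n_animals, cfg, agent, seed,
                           condition = "default") {
  stopifnot(n_animals >= 1)
  rows <- vector("list", n_animals)
  bins <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    id <- sprintf("%s_%03d", condition, i)
    log <- runSession(cfg, agent, seed = childSeed(seed, i), animal_id = id)
    ana <- analyzeLog(log)
    rows[[i]] <- cbind(ana$result, condition = condition,
                       stringsAsFactors = FALSE)
    bins[[i]] <- ana$bins
  }
  list(results = do.call(rbind, rows), bins = bins)
}
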