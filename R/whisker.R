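## Whisker-movement quantification. Gross whisker-field movement is
## summarized per frame by the average activation energy of a spatiotemporal
## Gabor filter bank, baseline-normalized by subtracting the mean of the low
## 20th percentile of pre-stimulus values, thresholded at mean + 3 SD of the
## normalized pre-stimulus baseline, and segmented into whisking bouts
## (supra-threshold runs lasting >= 0.5 s).

#' Build a spatial Gabor filter bank
#'
#' Quadrature (even/odd) Gabor pairs over a grid of orientations and spatial
#' frequencies. Defaults: 4 orientations x 3 spatial frequencies, 15 x 15
#' kernels — a small standard bank; every parameter is configurable.
#'
#' @param n_orientations Number of evenly spaced orientations in [0, pi).
#' @param spatial_freqs Spatial frequencies in cycles/pixel.
#' @param size Odd kernel side length (pixels).
#' @param sigma Gaussian envelope SD (pixels); default scales with the
#'   wavelength.
#' @return List of \code{list(even=, odd=)} kernel-matrix pairs with
#'   orientation/frequency attributes.
#' @export
gaborBank <- function(n_orientations = 4,
                      spatial_freqs = c(0.08, 0.16, 0.32),
                      size = 15, sigma = NULL) {
  stopifnot(size %% 2 == 1)
  half <- (size - 1) / 2
  g <- expand.grid(x = -half:half, y = -half:half)
  thetas <- seq(0, pi, length.out = n_orientations + 1)[seq_len(n_orientations)]
  bank <- list()
  for (th in thetas) {
    for (f in spatial_freqs) {
      s <- if (is.null(sigma)) 0.56 / f / 2 else sigma
      xr <- g$x * cos(th) + g$y * sin(th)
      yr <- -g$x * sin(th) + g$y * cos(th)
      env <- exp(-(xr^2 + yr^2) / (2 * s^2))
      even <- matrix(env * cos(2 * pi * f * xr), size, size)
      odd <- matrix(env * sin(2 * pi * f * xr), size, size)
      even <- even - mean(even)  # zero DC so flat fields give no response
      k <- list(even = even, odd = odd)
      attr(k, "theta") <- th
      attr(k, "freq") <- f
      bank[[length(bank) + 1L]] <- k
    }
  }
  bank
}

.asFrameArray <- function(frames) {
  if (is.list(frames)) {
    stopifnot(length(unique(vapply(frames, function(f)
      paste(dim(f), collapse = "x"), character(1)))) == 1L)
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1L]]), length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  frames
}

#' Motion energy of a grayscale video
#'
#' Convolves every frame with the spatial Gabor bank (via
#' \code{EBImage::filter2}), applies small temporal derivative filters to the
#' quadrature responses across frames, and averages the squared response
#' magnitude over pixels and filters to give one motion-energy value per
#' frame. A static video yields a constant (zero) trace; frames with
#' movement of the dominant structure — the whisker field in cropped videos
#' — yield elevated energy.
#'
#' @param frames 3-D numeric array (height x width x frames) or list of
#'   equally sized matrices; at least 2 frames.
#' @param bank Spatial filter bank from [gaborBank()].
#' @param temporal_filters List of numeric temporal convolution kernels
#'   (defaults: first difference and centered difference — two temporal
#'   frequency scales).
#' @param frame_rate_hz,stim_onset_frame,stim_duration_frames Metadata
#'   copied to the returned trace.
#' @return A raw (unnormalized) [MotionTrace-class].
#' @export
motionEnergy <- function(frames, bank = gaborBank(),
                         temporal_filters = list(c(-1, 1),
                                                 c(-0.5, 0, 0.5)),
                         frame_rate_hz = 30, stim_onset_frame = 1,
                         stim_duration_frames = 15) {
  frames <- .asFrameArray(frames)
  n_frames <- dim(frames)[3L]
  if (n_frames < 2L) stop("motion energy needs at least 2 frames")
  npix <- prod(dim(frames)[1:2])

  energy <- numeric(n_frames)
  for (k in bank) {
    E <- matrix(0, npix, n_frames)
    O <- matrix(0, npix, n_frames)
    for (t in seq_len(n_frames)) {
      fr <- frames[, , t]
      E[, t] <- as.numeric(EBImage::filter2(fr, k$even))
      O[, t] <- as.numeric(EBImage::filter2(fr, k$odd))
    }
    for (tf in temporal_filters) {
      L <- length(tf)
      valid <- seq_len(n_frames - L + 1L)
      dE <- matrix(0, npix, length(valid))
      dO <- matrix(0, npix, length(valid))
      for (j in seq_len(L)) {
        dE <- dE + tf[j] * E[, valid + j - 1L, drop = FALSE]
        dO <- dO + tf[j] * O[, valid + j - 1L, drop = FALSE]
      }
      e <- colMeans(dE^2 + dO^2)
      # align the filter output to its last tap (frame t gets the energy of
      # the change arriving at t) and replicate the edges to keep length
      lead <- as.integer(ceiling((L - 1L) / 2L))
      full <- c(rep(e[1L], lead), e,
                rep(e[length(e)], n_frames - length(e) - lead))
      energy <- energy + full
    }
  }
  MotionTrace(energy / (length(bank) * length(temporal_filters)),
              frame_rate_hz = frame_rate_hz,
              stim_onset_frame = stim_onset_frame,
              stim_duration_frames = stim_duration_frames,
              normalized = FALSE)
}

.preWindowValues <- function(trace, pre_window_s) {
  n_pre <- round(pre_window_s * trace@frame_rate_hz)
  first <- trace@stim_onset_frame - n_pre
  if (first < 1L)
    stop("insufficient pre-stimulus data: need ", n_pre,
         " frames before stimulus onset, have ",
         trace@stim_onset_frame - 1L)
  trace@values[first:(trace@stim_onset_frame - 1L)]
}

#' Baseline-normalize a motion-energy trace
#'
#' Averages the values at or below the 20th percentile of the pre-stimulus
#' window (default 1.2 s before stimulus onset) and subtracts that baseline
#' from every sample. Adding a constant offset to a raw trace leaves the
#' normalized trace unchanged.
#'
#' @param trace Raw [MotionTrace-class].
#' @param pre_window_s Pre-stimulus window length (s).
#' @param percentile Baseline percentile (default 0.2).
#' @return The normalized [MotionTrace-class].
#' @export
normalizeTrace <- function(trace, pre_window_s = 1.2, percentile = 0.2) {
  stopifnot(is(trace, "MotionTrace"))
  pre <- .preWindowValues(trace, pre_window_s)
  cutoff <- quantile(pre, percentile, names = FALSE)
  baseline <- mean(pre[pre <= cutoff])
  initialize(trace, values = trace@values - baseline, normalized = TRUE)
}

#' Whisking threshold of a normalized trace
#'
#' Mean + 3 SD of the normalized pre-stimulus baseline values. A
#' zero-variance pre-window is allowed (the threshold is then the mean).
#'
#' @param trace Normalized [MotionTrace-class].
#' @param pre_window_s Pre-stimulus window length (s).
#' @param n_sd Number of SDs above the mean (default 3).
#' @return Threshold value (same units as the trace).
#' @export
whiskingThreshold <- function(trace, pre_window_s = 1.2, n_sd = 3) {
  stopifnot(is(trace, "MotionTrace"))
  if (!trace@normalized)
    stop("the whisking threshold is defined on the normalized trace; ",
         "call normalizeTrace() first")
  pre <- .preWindowValues(trace, pre_window_s)
  s <- if (length(pre) > 1L) sd(pre) else 0
  mean(pre) + n_sd * s
}

#' Detect whisking bouts
#'
#' Finds maximal runs of samples strictly above the threshold and keeps those
#' lasting at least \code{min_duration_s}. Bout boundaries are at sample
#' resolution: a run of k frames spans \code{[(first-1)/rate, last/rate]} and
#' lasts \code{k/rate} seconds.
#'
#' @param trace Normalized [MotionTrace-class] (or numeric vector, in which
#'   case \code{frame_rate_hz} must be given).
#' @param threshold Whisking threshold (see [whiskingThreshold()]).
#' @param min_duration_s Minimum bout duration (s); default 0.5.
#' @param frame_rate_hz Frame rate, required when \code{trace} is numeric.
#' @return A [BoutSet-class].
#' @export
detectBouts <- function(trace, threshold, min_duration_s = 0.5,
                        frame_rate_hz = NULL) {
  if (is(trace, "MotionTrace")) {
    values <- trace@values
    rate <- trace@frame_rate_hz
  } else {
    values <- as.numeric(trace)
    if (is.null(frame_rate_hz))
      stop("frame_rate_hz is required for a bare numeric trace")
    rate <- frame_rate_hz
  }
  r <- rle(values > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate >= min_duration_s)
  b <- data.frame(start_s = (starts[keep] - 1L) / rate,
                  end_s = ends[keep] / rate,
                  duration_s = r$lengths[keep] / rate)
  new("BoutSet", bouts = b, threshold = threshold,
      min_duration_s = min_duration_s)
}

#' Percent of trials with post-stimulus whisking
#'
#' A trial counts as whisking when at least one detected bout overlaps the
#' post-stimulus window (default 1-2 s after air-puff onset) by at least
#' \code{min_overlap_s}. For each raw trace the pipeline is: normalize,
#' threshold, detect bouts, test overlap.
#'
#' @param traces List of [MotionTrace-class] objects (raw traces are
#'   normalized internally).
#' @param window Window after stimulus onset, \code{c(from_s, to_s)}.
#' @param min_overlap_s Minimum bout overlap with the window (s).
#' @param min_duration_s Minimum bout duration (s).
#' @param pre_window_s Baseline window for normalization/threshold (s).
#' @return Percentage in [0, 100].
#' @export
percentWhisking <- function(traces, window = c(1, 2), min_overlap_s = 0.5,
                            min_duration_s = 0.5, pre_window_s = 1.2) {
  if (!length(traces)) stop("percentWhisking needs at least one trial")
  whisked <- vapply(traces, function(tr) {
    stopifnot(is(tr, "MotionTrace"))
    if (!tr@normalized) tr <- normalizeTrace(tr, pre_window_s)
    th <- whiskingThreshold(tr, pre_window_s)
    b <- bouts(detectBouts(tr, th, min_duration_s))
    if (!nrow(b)) return(FALSE)
    onset_s <- (tr@stim_onset_frame - 1L) / tr@frame_rate_hz
    lo <- onset_s + window[1L]; hi <- onset_s + window[2L]
    any(pmin(b$end_s, hi) - pmax(b$start_s, lo) >= min_overlap_s)
  }, logical(1))
  100 * mean(whisked)
}

#' Tip displacement trace and area under the curve
#'
#' The rest position is the mean tip coordinate over the pre-stimulus
#' frames; displacement is the per-frame Euclidean distance from rest
#' (non-negative by construction), and the area is the trapezoidal integral
#' of the displacement over the stimulus window, in coordinate-units x
#' seconds.
#'
#' @param track [WhiskerTrack-class] (gap-free; gaps are constructor
#'   errors — no interpolation is performed).
#' @param stim_window Frame range \code{c(from, to)} (1-based, inclusive);
#'   default: stimulus onset frame to end of track.
#' @return List with \code{displacement} (per-frame numeric) and \code{area}.
#' @export
displacementArea <- function(track, stim_window = NULL) {
  stopifnot(is(track, "WhiskerTrack"))
  validObject(track)
  if (is.null(stim_window))
    stim_window <- c(track@stim_onset_frame, length(track@frame))
  if (stim_window[1L] < 1L || stim_window[2L] > length(track@frame) ||
      stim_window[1L] >= stim_window[2L])
    stop("track does not cover the requested stimulus window")
  pre <- track@frame < track@stim_onset_frame
  if (!any(pre)) pre <- seq_along(track@frame) == 1L
  rest <- c(mean(track@x[pre]), mean(track@y[pre]))
  disp <- sqrt((track@x - rest[1L])^2 + (track@y - rest[2L])^2)
  idx <- stim_window[1L]:stim_window[2L]
  dt <- 1 / track@frame_rate_hz
  d <- disp[idx]
  area <- sum((d[-1L] + d[-length(d)]) / 2) * dt
  list(displacement = disp, area = area)
}

#' Render a synthetic whisker video
#'
#' Draws a bright curvilinear filament on a dark background whose free tip
#' follows a specified deflection profile, with optional Gaussian pixel
#' noise — a stand-in for cropped whisker-field videos, with ground truth
#' attached for end-to-end tests. This generator is synthetic by design; it
#' emulates a single dominant moving structure, not a full whisker field.
#'
#' @param n_frames Number of frames.
#' @param deflection Numeric vector (length \code{n_frames}) of tip
#'   deflections in pixels (0 = rest).
#' @param width,height Frame size in pixels.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param stream An [rngStream()] for the noise (required if
#'   \code{noise_sd > 0}).
#' @param frame_rate_hz,stim_onset_frame,stim_duration_frames Metadata.
#' @return List with \code{frames} (height x width x frames array, values
#'   in [0, 1] plus noise), \code{track} (ground-truth
#'   [WhiskerTrack-class]), \code{frame_rate_hz}.
#' @export
synthWhiskerVideo <- function(n_frames = 90, deflection = rep(0, n_frames),
                              width = 48, height = 48, noise_sd = 0,
                              stream = NULL, frame_rate_hz = 30,
                              stim_onset_frame = 1,
                              stim_duration_frames = 15) {
  stopifnot(length(deflection) == n_frames, n_frames >= 2)
  base_x <- round(width * 0.15)
  base_y <- round(height / 2)
  len <- round(width * 0.6)
  s <- seq(0, 1, length.out = 4 * len)
  frames <- array(0, dim = c(height, width, n_frames))
  tip_x <- numeric(n_frames); tip_y <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    px <- base_x + s * len
    py <- base_y + s^2 * deflection[t]
    tip_x[t] <- px[length(px)]
    tip_y[t] <- py[length(py)]
    ix <- round(px); iy <- round(py)
    ok <- ix >= 1 & ix <= width & iy >= 1 & iy <= height
    fr <- matrix(0, height, width)
    fr[cbind(iy[ok], ix[ok])] <- 1
    # thicken by one pixel vertically for a ~2 px wide filament
    ok2 <- ok & iy + 1 <= height
    fr[cbind(iy[ok2] + 1L, ix[ok2])] <- 1
    frames[, , t] <- fr
  }
  if (noise_sd > 0) {
    if (is.null(stream)) stop("a random stream is required for noisy frames")
    frames <- frames + withStream(
      stream, array(rnorm(length(frames), 0, noise_sd), dim = dim(frames)))
  }
  list(frames = frames,
       track = WhiskerTrack(seq_len(n_frames), tip_x, tip_y,
                            frame_rate_hz = frame_rate_hz,
                            stim_onset_frame = stim_onset_frame),
       frame_rate_hz = frame_rate_hz)
}
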