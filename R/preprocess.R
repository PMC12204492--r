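#' Neuropil correction
#'
#' Subtracts the neuropil signal scaled by `r` from the raw fluorescence,
#' elementwise: `F - r * F_neu`.
#'
#' @param F raw fluorescence matrix (neurons x frames) or vector.
#' @param F_neu neuropil matrix/vector, same shape.
#' @param r scale factor in `[0, 1]` (default 0.7).
#' @return corrected matrix/vector.
#' @export
neuropil_correct <- function(F, F_neu, r = 0.7) {
  if (!identical(dim(F), dim(F_neu)) || length(F) != length(F_neu)) {
    stop("neuropil correction: shape mismatch between F and F_neu")
  }
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  F - r * F_neu
}

#' Sliding-percentile dF/F
#'
#' The running baseline `F0(t)` is the `pct`-th percentile of the trace in
#' a centered window of `window_s` seconds around each frame (truncated at
#' the recording edges, linear interpolation between order statistics);
#' the result is `(F - F0) / F0`.
#'
#' @param trace positive numeric vector.
#' @param frame_rate_hz sampling rate.
#' @param window_s baseline window length in seconds (default 25).
#' @param pct baseline percentile (default 10).
#' @return dF/F vector, same length as `trace`.
#' @export
sliding_dff <- function(trace, frame_rate_hz, window_s = 25, pct = 10) {
  n <- length(trace)
  w <- round(window_s * frame_rate_hz)
  if (n <= w) stop("trace shorter than the baseline window")
  half <- w %/% 2
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    unname(stats::quantile(trace[lo:hi], pct / 100, names = FALSE))
  }, numeric(1))
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop("nonpositive baseline F0 at frame ", bad[1],
         "; dF/F requires a positive trace")
  }
  (trace - f0) / f0
}

#' Session-level normalization: splice, interpolate, z-score
#'
#' Concatenates per-trial dF/F traces in temporal order, linearly
#' interpolates frames flagged as dropped, then z-scores the whole
#' session-length trace.
#'
#' @param dff_per_trial list of numeric vectors (or one vector).
#' @param dropped_mask optional logical vector over the concatenated trace.
#' @return z-scored vector (mean 0, SD 1).
#' @export
normalize_session <- function(dff_per_trial, dropped_mask = NULL) {
  x <- if (is.list(dff_per_trial)) {
    unlist(dff_per_trial, use.names = FALSE)
  } else as.numeric(dff_per_trial)
  if (!is.null(dropped_mask)) {
    if (length(dropped_mask) != length(x)) stop("mask length mismatch")
    if (all(dropped_mask)) stop("all frames masked; nothing to normalize")
    x <- interpolate_masked(x, dropped_mask)
  }
  if (sum(is.finite(x)) < 2) stop("need at least 2 finite samples")
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance trace cannot be z-scored")
  (x - mean(x)) / s
}

interpolate_masked <- function(x, mask) {
  idx <- which(!mask)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Preprocess a session bundle into z-scored traces
#'
#' Applies neuropil correction when a neuropil matrix is present, optional
#' sliding-percentile dF/F (for raw-fluorescence traces; synthetic traces
#' in signal units skip it), dropped-frame interpolation, and session-wide
#' z-scoring per neuron. Stores the result in `bundle$z`.
#'
#' @param bundle `session_bundle`.
#' @param dff apply [sliding_dff()] per neuron before z-scoring.
#' @param window_s,pct baseline parameters for [sliding_dff()].
#' @return the bundle with `$z` set (neurons x frames, mean 0 / SD 1 rows).
#' @export
preprocess_session <- function(bundle, dff = FALSE, window_s = 25, pct = 10) {
  tr <- bundle$traces
  if (!is.null(bundle$neuropil)) tr <- neuropil_correct(tr, bundle$neuropil)
  z <- t(apply(tr, 1, function(x) {
    if (dff) x <- sliding_dff(x, bundle$frame_rate_hz, window_s, pct)
    normalize_session(x, bundle$dropped_frame_mask)
  }))
  bundle$z <- z
  bundle
}

#' Isosbestic (405 nm) correction of a photometry signal
#'
#' Smooths and detrends both channels, fits the 405-nm reference onto the
#' 465-nm signal by least-squares affine regression, subtracts the fit and
#' divides by it: `100 * (sig465 - fit405) / fit405` (dF/F in percent).
#'
#' @param sig465,sig405 equal-length numeric vectors, already at 30 Hz.
#' @param rate_hz sampling rate (for the smoothing kernel).
#' @param smooth_sd_s Gaussian smoothing SD in seconds (0 disables).
#' @param detrend remove a linear time trend from each channel first.
#' @return corrected dF/F (%) vector.
#' @export
isosbestic_correct <- function(sig465, sig405, rate_hz = 30,
                               smooth_sd_s = 0.1, detrend = TRUE) {
  if (length(sig465) != length(sig405)) stop("channel length mismatch")
  n <- length(sig465)
  prep <- function(x, keep_mean = FALSE) {
    if (smooth_sd_s > 0) x <- conv_same(x, gaussian_kernel(smooth_sd_s * rate_hz))
    if (detrend) {
      t <- seq_len(n)
      fit <- stats::lm.fit(cbind(1, t), x)
      x <- x - fit$fitted.values + mean(x)
    }
    x
  }
  s465 <- prep(sig465)
  s405 <- prep(sig405)
  if (stats::sd(s405) < 1e-12) {
    stop("degenerate (constant) 405 nm channel; cannot fit reference")
  }
  co <- stats::lm.fit(cbind(1, s405), s465)$coefficients
  fit405 <- co[1] + co[2] * s405
  # offset the fitted reference away from zero crossings: the division
  # needs a positive baseline, so express it around the channel mean
  denom <- fit405
  if (any(abs(denom) < 1e-9)) {
    stop("fitted 405 reference crosses zero; rescale inputs to a positive baseline")
  }
  100 * (s465 - fit405) / denom
}

#' Kinematics from a behavior track
#'
#' Speed is the magnitude of the Gaussian-smoothed positional derivative
#' (15-frame / 0.5-s kernel support at 30 Hz). Avoidance-run onsets are
#' the first frame within each CS at which speed reaches `run_thresh`
#' (5 cm/s); freezing bouts are maximal runs below 0.25 cm/s lasting at
#' least 0.5 s; flight frames exceed 50 cm/s.
#'
#' @param track `behavior_track`.
#' @param events optional `event_table` for run-onset detection.
#' @param run_thresh,freeze_thresh,flight_thresh cm/s thresholds.
#' @param freeze_min_s minimum freezing-bout duration (s).
#' @return list with `speed` (cm/s per frame), `t_s`, `avrun_onsets_s`
#'   (per trial, `NA` when no crossing), `freezing_bouts`
#'   (data.frame onset/offset s), `flight_frames`.
#' @export
kinematics <- function(track, events = NULL, run_thresh = 5,
                       freeze_thresh = 0.25, flight_thresh = 50,
                       freeze_min_s = 0.5) {
  fr <- track$frame_rate_hz
  n <- nrow(track$xy)
  if (n < 16) stop("behavior track too short for kinematics")
  k <- gaussian_kernel(sd_frames = 15 / 6, support_frames = 15)
  xs <- conv_same(track$xy[, 1], k)
  ys <- conv_same(track$xy[, 2], k)
  # central-difference derivative
  dx <- (c(xs[-1], xs[n]) - c(xs[1], xs[-n])) * fr / 2
  dy <- (c(ys[-1], ys[n]) - c(ys[1], ys[-n])) * fr / 2
  speed <- sqrt(dx^2 + dy^2)
  t_s <- (seq_len(n) - 1) / fr
  onsets <- NULL
  if (!is.null(events)) {
    onsets <- vapply(seq_len(nrow(events)), function(i) {
      lo <- events$cs_onset_s[i]
      hi <- if (is.finite(events$avrun_onset_s[i])) {
        events$avrun_onset_s[i] + 3
      } else events$cs_offset_s[i]
      in_win <- which(t_s >= lo & t_s < hi & speed >= run_thresh)
      if (length(in_win)) t_s[in_win[1]] else NA_real_
    }, numeric(1))
  }
  frozen <- speed < freeze_thresh
  r <- rle(frozen)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / fr >= freeze_min_s)
  freezing <- data.frame(onset_s = t_s[starts[keep]],
                         offset_s = t_s[ends[keep]] + 1 / fr)
  list(speed = speed, t_s = t_s, avrun_onsets_s = onsets,
       freezing_bouts = freezing,
       flight_frames = which(speed > flight_thresh))
}

#' Event-aligned trial tensor
#'
#' Slices the z-scored session traces around each trial's alignment event
#' into a neurons x trials x time array. Success trials with avoidance
#' latency below `exclude_fast_avoid_s` are dropped (their CS and run
#' signals are not separable); trials lacking the alignment event or whose
#' window leaves the recording are dropped with a message.
#'
#' @param session preprocessed `session_bundle` (needs `$z`).
#' @param align_event "cs_onset", "avrun_onset" or "shock_onset".
#' @param window_s numeric `(pre, post)` in seconds relative to the event
#'   (pre is negative), half-open `[pre, post)`.
#' @param exclude_fast_avoid_s fast-avoidance exclusion latency (s).
#' @return list of class `trial_tensor`: `data` (array), `align_event`,
#'   `window_s`, `outcome`, `frame_rate_hz`, `trial_index`, `t_s`.
#' @export
build_trial_tensor <- function(session, align_event = "cs_onset",
                               window_s = c(-2, 3),
                               exclude_fast_avoid_s = 4) {
  if (is.null(session$z)) stop("run preprocess_session() first")
  fr <- session$frame_rate_hz
  ev <- session$events
  times <- switch(align_event,
                  cs_onset = ev$cs_onset_s,
                  avrun_onset = ev$avrun_onset_s,
                  shock_onset = ev$shock_onset_s,
                  stop("unknown align_event: ", align_event))
  lat <- ev$avrun_onset_s - ev$cs_onset_s
  fast <- ev$outcome == "success" & is.finite(lat) &
    lat < exclude_fast_avoid_s
  n_t <- round((window_s[2] - window_s[1]) * fr)
  n_frames <- ncol(session$z)
  keep <- logical(nrow(ev))
  starts <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (fast[i] || !is.finite(times[i])) next
    a <- floor((times[i] + window_s[1]) * fr) + 1L
    if (a < 1 || a + n_t - 1 > n_frames) {
      message("trial ", ev$trial_index[i], ": window outside recording, dropped")
      next
    }
    keep[i] <- TRUE
    starts[i] <- a
  }
  if (!any(keep)) stop("no trials survive alignment to ", align_event)
  idx <- which(keep)
  data <- array(NA_real_, c(nrow(session$z), length(idx), n_t))
  for (j in seq_along(idx)) {
    a <- starts[idx[j]]
    data[, j, ] <- session$z[, a:(a + n_t - 1), drop = FALSE]
  }
  structure(list(data = data, align_event = align_event,
                 window_s = window_s, outcome = ev$outcome[idx],
                 frame_rate_hz = fr, trial_index = ev$trial_index[idx],
                 start_frames = starts[idx],
                 t_s = window_s[1] + (seq_len(n_t) - 0.5) / fr),
            class = "trial_tensor")
}

#' Subset a trial tensor by outcome
#'
#' @param tensor `trial_tensor`.
#' @param outcome "success" or "failure".
#' @return `trial_tensor` with only the matching trials.
#' @export
tensor_by_outcome <- function(tensor, outcome) {
  sel <- tensor$outcome == outcome
  if (!any(sel)) stop("no ", outcome, " trials in tensor")
  tensor$data <- tensor$data[, sel, , drop = FALSE]
  tensor$trial_index <- tensor$trial_index[sel]
  tensor$outcome <- tensor$outcome[sel]
  tensor
}
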