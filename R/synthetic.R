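#' Response-motif specification for the synthetic generator
#'
#' A motif describes one phenotype of event-locked response: per-event
#' amplitudes (z-units), whether the response is transient (impulse at the
#' event) or sustained (boxcar over the event), and a Gaussian anatomical
#' locus from which member neurons draw their coordinates.
#'
#' @param name motif label.
#' @param event_weights named numeric vector over event types
#'   `cs_success`, `cs_failure`, `shock`, `avrun_onset`,
#'   `avrun_anticipatory`, `safe_entry` (missing types count as 0).
#' @param persistence "transient" or "sustained" (CS responses only;
#'   point events are always transient).
#' @param spatial_center AP/ML/DV center (mm).
#' @param spatial_sd isotropic SD of member coordinates (mm).
#' @return list of class `motif_spec`.
#' @export
motif_spec <- function(name, event_weights, persistence = "transient",
                       spatial_center = c(0.5, 0.4, 3.0), spatial_sd = 0.15) {
  ev_types <- c("cs_success", "cs_failure", "shock", "avrun_onset",
                "avrun_anticipatory", "safe_entry")
  w <- setNames(numeric(length(ev_types)), ev_types)
  if (length(event_weights)) {
    bad <- setdiff(names(event_weights), ev_types)
    if (length(bad)) stop("unknown event types: ", paste(bad, collapse = ", "))
    w[names(event_weights)] <- event_weights
  }
  if (!all(is.finite(w))) stop("motif amplitudes must be finite")
  if (spatial_sd <= 0) stop("spatial_sd must be positive")
  persistence <- match.arg(persistence, c("transient", "sustained"))
  structure(list(name = name, event_weights = w, persistence = persistence,
                 spatial_center = spatial_center, spatial_sd = spatial_sd),
            class = "motif_spec")
}

#' Default motif dictionary
#'
#' Ten motifs spanning the phenomenology seen in lateral-septum recordings
#' during avoidance: CS-activated cells biased toward one outcome,
#' CS-suppressed cells, unresponsive cells, pre-run ramping, run-onset,
#' shock-responsive, mixed shock/cue, and safety-arrival responses. Mixing
#' proportions follow the relative sizes of the ten functional clusters
#' reported for this circuit (181, 106, 82, 81, 429, 246, 83, 150, 151,
#' 145 neurons), purely for realism of class imbalance.
#'
#' @return list with `motifs` (list of `motif_spec`) and `proportions`.
#' @export
default_motifs <- function() {
  # amplitudes are calibrated so every responsive motif's noiseless
  # trial-averaged epoch template has comparable norm (~10 z*frames at
  # 5 Hz, 30 trials): planted clusters are then comparably separated,
  # which is the generator's contract for recovery tests
  m <- list(
    motif_spec("cs_act_success", c(cs_success = 0.60, cs_failure = 0.22),
               "sustained", c(0.85, 0.30, 2.6), 0.12),
    motif_spec("cs_act_failure", c(cs_success = 0.19, cs_failure = 0.52),
               "sustained", c(0.60, 0.45, 2.8), 0.12),
    motif_spec("cs_sup_transient", c(cs_success = -4.5, cs_failure = -4.5),
               "transient", c(0.40, 0.25, 3.0), 0.12),
    motif_spec("cs_sup_sustained", c(cs_success = -0.41, cs_failure = -0.41),
               "sustained", c(0.25, 0.50, 3.2), 0.12),
    motif_spec("unresponsive", c(cs_success = 0),
               "transient", c(0.50, 0.40, 3.0), 0.40),
    motif_spec("run_onset", c(avrun_onset = 5.7),
               "transient", c(0.70, 0.20, 3.4), 0.12),
    motif_spec("pre_run_ramp", c(avrun_anticipatory = 5.2),
               "transient", c(0.15, 0.35, 2.7), 0.12),
    motif_spec("shock_act", c(shock = 6.2),
               "transient", c(0.95, 0.45, 3.1), 0.12),
    motif_spec("shock_cue_mixed", c(shock = 4.5, cs_failure = 0.26),
               "sustained", c(0.35, 0.55, 3.5), 0.12),
    motif_spec("safe_entry", c(safe_entry = 6.7),
               "transient", c(0.10, 0.15, 3.3), 0.12))
  sizes <- c(181, 106, 82, 81, 429, 246, 83, 150, 151, 145)
  list(motifs = m, proportions = sizes / sum(sizes))
}

#' Simulation configuration
#'
#' Defaults reproduce the task conditions the analyses assume: 30 trials
#' per session, a 10-s CS ceiling, inter-trial intervals uniform on
#' 25-40 s, success probability 0.7 (a trained animal past the 33%
#' criterion), unit-SD Gaussian noise in z-units, and a slow random-walk
#' baseline.
#'
#' @param n_neurons,n_trials,n_sessions session dimensions.
#' @param frame_rate_hz imaging rate (5 or 20 Hz).
#' @param p_success per-trial success probability.
#' @param iti_range_s inter-trial interval range (s).
#' @param cs_max_s CS duration ceiling (s).
#' @param noise_sd Gaussian noise SD added per frame (z-units).
#' @param baseline_drift_sd random-walk innovation SD per second.
#' @param amplitude_jitter_sd lognormal SD of per-neuron amplitude scaling
#'   (0 = all members share the motif amplitudes exactly).
#' @param motifs list as returned by [default_motifs()].
#' @param anticipation_s lead time of the anticipatory ramp before run onset.
#' @param run_duration_s duration of the shuttle run (safety arrival at its
#'   end).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 40, n_trials = 30, n_sessions = 1,
                       frame_rate_hz = 5, p_success = 0.7,
                       iti_range_s = c(25, 40), cs_max_s = 10,
                       noise_sd = 1, baseline_drift_sd = 0.02,
                       amplitude_jitter_sd = 0,
                       motifs = default_motifs(),
                       anticipation_s = 1, run_duration_s = 1,
                       seed = 1L) {
  stopifnot(n_neurons >= 1, n_trials >= 1, n_sessions >= 1,
            p_success >= 0, p_success <= 1, frame_rate_hz > 0,
            noise_sd >= 0, baseline_drift_sd >= 0)
  if (abs(sum(motifs$proportions) - 1) > 1e-8) {
    stop("motif mixing proportions must sum to 1")
  }
  structure(list(n_neurons = n_neurons, n_trials = n_trials,
                 n_sessions = n_sessions, frame_rate_hz = frame_rate_hz,
                 p_success = p_success, iti_range_s = iti_range_s,
                 cs_max_s = cs_max_s, noise_sd = noise_sd,
                 baseline_drift_sd = baseline_drift_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 motifs = motifs, anticipation_s = anticipation_s,
                 run_duration_s = run_duration_s, seed = as.integer(seed)),
            class = "sim_config")
}

# Draw the trial timeline: CS onsets after 25-40 s ITIs, Bernoulli outcomes,
# success latencies uniform on [4, 10) s (the 10-s ceiling is the task's;
# the latency law itself is a modeling choice), failures shocked at CS+10 s
# with an escape run up to 2 s later.
sim_trial_timeline <- function(cfg) {
  n <- cfg$n_trials
  outcome <- ifelse(stats::runif(n) < cfg$p_success, "success", "failure")
  iti <- stats::runif(n, cfg$iti_range_s[1], cfg$iti_range_s[2])
  cs_onset <- 10 + cumsum(iti) + c(0, cumsum(rep(cfg$cs_max_s + 5, n - 1)))
  latency <- ifelse(outcome == "success",
                    stats::runif(n, 4, cfg$cs_max_s),
                    NA_real_)
  avrun <- ifelse(outcome == "success", cs_onset + latency,
                  cs_onset + cfg$cs_max_s + stats::runif(n, 0.3, 2))
  cs_offset <- ifelse(outcome == "success", cs_onset + latency,
                      cs_onset + cfg$cs_max_s)
  shock <- ifelse(outcome == "failure", cs_onset + cfg$cs_max_s, NA_real_)
  event_table(seq_len(n), cs_onset, cs_offset, outcome,
              shock_onset_s = shock, avrun_onset_s = avrun,
              cs_max_s = cfg$cs_max_s)
}

# Event regressor trains on the imaging frame grid, kernel-convolved.
# Sustained CS responses use a boxcar over the tone; point events are
# impulses; the anticipatory regressor leads the run onset.
sim_event_regressors <- function(events, cfg, n_frames) {
  fr <- cfg$frame_rate_hz
  kern <- gcamp_kernel(fr)
  to_frame <- function(t) {
    t <- t[is.finite(t)]
    f <- floor(t * fr) + 1L
    f[f >= 1 & f <= n_frames]
  }
  succ <- events$outcome == "success"
  impulse_train <- function(frames) {
    x <- numeric(n_frames); x[frames] <- 1; x
  }
  boxcar_train <- function(on, off) {
    x <- numeric(n_frames)
    for (i in seq_along(on)) {
      a <- floor(on[i] * fr) + 1L
      b <- min(n_frames, floor(off[i] * fr))
      if (a <= b && a >= 1) x[a:b] <- 1
    }
    x
  }
  conv <- function(x) {
    out <- stats::convolve(x, rev(kern), type = "open")[seq_len(n_frames)]
    out[abs(out) < 1e-12] <- 0
    out
  }
  safe_t <- events$avrun_onset_s + cfg$run_duration_s
  list(
    cs_success_imp = conv(impulse_train(to_frame(events$cs_onset_s[succ]))),
    cs_failure_imp = conv(impulse_train(to_frame(events$cs_onset_s[!succ]))),
    cs_success_box = conv(boxcar_train(events$cs_onset_s[succ],
                                       events$cs_offset_s[succ])),
    cs_failure_box = conv(boxcar_train(events$cs_onset_s[!succ],
                                       events$cs_offset_s[!succ])),
    shock = conv(impulse_train(to_frame(events$shock_onset_s))),
    avrun_onset = conv(impulse_train(to_frame(events$avrun_onset_s))),
    avrun_anticipatory = conv(impulse_train(to_frame(
      events$avrun_onset_s - cfg$anticipation_s))),
    safe_entry = conv(impulse_train(to_frame(safe_t))))
}

sim_motif_signal <- function(motif, regs, amp_scale = 1) {
  w <- motif$event_weights * amp_scale
  cs_s <- if (motif$persistence == "sustained") regs$cs_success_box else
    regs$cs_success_imp
  cs_f <- if (motif$persistence == "sustained") regs$cs_failure_box else
    regs$cs_failure_imp
  w["cs_success"] * cs_s + w["cs_failure"] * cs_f +
    w["shock"] * regs$shock + w["avrun_onset"] * regs$avrun_onset +
    w["avrun_anticipatory"] * regs$avrun_anticipatory +
    w["safe_entry"] * regs$safe_entry
}

# Behavior track: the animal shuttles along x at each run onset with a
# speed profile that is linear through the 5 cm/s detection threshold
# exactly at the planted onset (0 at onset-0.25 s up to 20 cm/s at
# onset+0.75 s, back to rest by onset+1.5 s).
sim_behavior_track <- function(events, duration_s, track_rate = 30,
                               noise_sd = 0) {
  n <- ceiling(duration_s * track_rate)
  t <- (seq_len(n) - 1) / track_rate
  speed <- numeric(n)
  dirn <- 1
  x <- numeric(n)
  runs <- events$avrun_onset_s[is.finite(events$avrun_onset_s)]
  for (on in runs) {
    prof <- numeric(n)
    up <- t >= (on - 0.25) & t < (on + 0.75)
    prof[up] <- 20 * (t[up] - (on - 0.25)) / 1.0
    down <- t >= (on + 0.75) & t < (on + 1.5)
    prof[down] <- 20 * (1 - (t[down] - (on + 0.75)) / 0.75)
    speed <- speed + prof * dirn
    dirn <- -dirn
  }
  x <- cumsum(speed) / track_rate
  y <- rep(10, n)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, noise_sd)
    y <- y + stats::rnorm(n, 0, noise_sd)
  }
  behavior_track(cbind(x + 5, y), frame_rate_hz = track_rate)
}

#' Generate one synthetic session with planted ground truth
#'
#' Trial outcomes are Bernoulli draws; each neuron is assigned a response
#' motif and its noiseless trace is the motif's amplitude-weighted sum of
#' kernel-convolved event trains, plus Gaussian noise and a slow
#' random-walk baseline. The behavior track crosses the 5 cm/s run
#' threshold exactly at each planted run onset.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return a `session_bundle` with a `ground_truth` element: per-neuron
#'   motif assignment and amplitudes, the noiseless signal matrix, and the
#'   planted latencies.
#' @export
generate_session <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  if (cfg$p_success %in% c(0, 1)) {
    warning("p_success of ", cfg$p_success,
            " yields single-class sessions; outcome decoders will fail")
  }
  events <- sim_trial_timeline(cfg)
  duration <- max(events$cs_offset_s, events$avrun_onset_s,
                  events$shock_onset_s, na.rm = TRUE) + 15
  n_frames <- ceiling(duration * cfg$frame_rate_hz)
  regs <- sim_event_regressors(events, cfg, n_frames)
  nm <- length(cfg$motifs$motifs)
  motif_id <- sample.int(nm, cfg$n_neurons, replace = TRUE,
                         prob = cfg$motifs$proportions)
  amp_scale <- if (cfg$amplitude_jitter_sd > 0) {
    exp(stats::rnorm(cfg$n_neurons, 0, cfg$amplitude_jitter_sd))
  } else rep(1, cfg$n_neurons)
  signal <- matrix(0, cfg$n_neurons, n_frames)
  coords <- matrix(NA_real_, cfg$n_neurons, 3)
  for (i in seq_len(cfg$n_neurons)) {
    mo <- cfg$motifs$motifs[[motif_id[i]]]
    signal[i, ] <- sim_motif_signal(mo, regs, amp_scale[i])
    coords[i, ] <- stats::rnorm(3, mo$spatial_center, mo$spatial_sd)
  }
  traces <- signal
  if (cfg$noise_sd > 0) {
    traces <- traces + matrix(stats::rnorm(length(signal), 0, cfg$noise_sd),
                              nrow(signal))
  }
  if (cfg$baseline_drift_sd > 0) {
    step_sd <- cfg$baseline_drift_sd / sqrt(cfg$frame_rate_hz)
    drift <- t(apply(matrix(stats::rnorm(length(signal), 0, step_sd),
                            nrow(signal)), 1, cumsum))
    traces <- traces + drift
  }
  neurons <- data.frame(neuron_id = sprintf("n%04d", seq_len(cfg$n_neurons)),
                        ap_mm = coords[, 1], ml_mm = coords[, 2],
                        dv_mm = coords[, 3], subtype = "none",
                        stringsAsFactors = FALSE)
  behavior <- sim_behavior_track(events, duration)
  b <- session_bundle(traces, cfg$frame_rate_hz, events,
                      behavior = behavior, neurons = neurons)
  motif_names <- vapply(cfg$motifs$motifs, `[[`, "", "name")
  amps <- t(vapply(seq_len(cfg$n_neurons), function(i) {
    cfg$motifs$motifs[[motif_id[i]]]$event_weights * amp_scale[i]
  }, cfg$motifs$motifs[[1]]$event_weights))
  b$ground_truth <- list(
    motif_id = motif_id, motif_name = motif_names[motif_id],
    amplitudes = amps, signal = signal,
    avrun_latency_s = events$avrun_onset_s - events$cs_onset_s,
    latency_model = "uniform[4,10) s on success; shock+U(0.3,2) s escape on failure (modeling choice)",
    outcome = events$outcome, seed = seed)
  b
}

#' Generate a cohort of independent sessions sharing the motif dictionary
#'
#' @param cfg a [sim_config()]; `cfg$n_sessions` is overridden by
#'   `n_sessions` when given.
#' @param n_sessions number of sessions.
#' @return list of `session_bundle`s; session `i` uses seed
#'   `cfg$seed + i - 1`.
#' @export
generate_cohort <- function(cfg, n_sessions = cfg$n_sessions) {
  lapply(seq_len(n_sessions), function(i) {
    s <- generate_session(cfg, seed = cfg$seed + i - 1L)
    s$session_id <- sprintf("s%03d", i)
    s$animal_id <- sprintf("a%03d", i)
    s
  })
}

#' Generate a two-channel photometry recording
#'
#' The 465-nm channel carries the kernel-convolved event signal plus a
#' shared low-pass motion artifact and white noise; the 405-nm channel
#' carries the scaled artifact plus noise but no signal, so isosbestic
#' regression is testable against ground truth.
#'
#' @param cfg a [sim_config()] (trial structure and seed).
#' @param region_weights named amplitudes over event types, as in
#'   [motif_spec()].
#' @param artifact_sd SD of the shared motion artifact (0 disables it).
#' @param artifact_gain_405 artifact gain on the 405 channel relative to 465.
#' @param noise_sd channel white-noise SD.
#' @param rate_hz photometry rate after downsampling (30 Hz).
#' @param region afferent region label.
#' @return list of class `photometry_recording` with `sig465`, `sig405`,
#'   `events`, `rate_hz`, `region` and `ground_truth` (signal, artifact).
#' @export
generate_photometry <- function(cfg, region_weights, artifact_sd = 0.5,
                                artifact_gain_405 = 0.8, noise_sd = 0.05,
                                rate_hz = 30, region = "afferent") {
  if (!all(is.finite(region_weights))) stop("region weights must be finite")
  set.seed(cfg$seed)
  events <- sim_trial_timeline(cfg)
  duration <- max(events$cs_offset_s, events$avrun_onset_s,
                  events$shock_onset_s, na.rm = TRUE) + 15
  n <- ceiling(duration * rate_hz)
  pcfg <- cfg; pcfg$frame_rate_hz <- rate_hz
  regs <- sim_event_regressors(events, pcfg, n)
  mo <- motif_spec("photometry", region_weights, "transient")
  signal <- sim_motif_signal(mo, regs)
  artifact <- numeric(n)
  if (artifact_sd > 0) {
    raw <- stats::rnorm(n)
    g <- gaussian_kernel(sd_frames = 0.5 * rate_hz)
    sm <- conv_same(raw, g)
    artifact <- artifact_sd * sm / stats::sd(sm)
  }
  sig465 <- signal + artifact + stats::rnorm(n, 0, noise_sd)
  sig405 <- artifact_gain_405 * artifact + stats::rnorm(n, 0, noise_sd)
  structure(list(sig465 = sig465, sig405 = sig405, events = events,
                 rate_hz = rate_hz, region = region,
                 ground_truth = list(signal = signal, artifact = artifact)),
            class = "photometry_recording")
}

#' Generate a subjects x regions presynaptic input-count matrix
#'
#' Per subject, region proportions are Dirichlet draws around the
#' subject's subtype profile and counts are a multinomial of `total_cells`.
#'
#' @param n_subjects_per_subtype subjects per subtype.
#' @param region_profiles named list, subtype -> named mean-proportion
#'   vector over a common region list (each sums to 1).
#' @param concentration Dirichlet concentration (higher = tighter around
#'   the profile).
#' @param total_cells input cells counted per subject.
#' @param seed RNG seed.
#' @return list of class `input_count_matrix` with `counts`
#'   (subjects x regions), `subtype`, `region_names`.
#' @export
generate_input_counts <- function(n_subjects_per_subtype, region_profiles,
                                  concentration = 100, total_cells = 2000,
                                  seed = 1L) {
  stopifnot(concentration > 0)
  regions <- names(region_profiles[[1]])
  for (p in region_profiles) {
    if (!identical(names(p), regions)) {
      stop("config error: region lists differ across subtype profiles")
    }
  }
  set.seed(seed)
  subtypes <- names(region_profiles)
  counts <- NULL
  subj_subtype <- character()
  for (st in subtypes) {
    prof <- region_profiles[[st]] / sum(region_profiles[[st]])
    for (j in seq_len(n_subjects_per_subtype)) {
      g <- stats::rgamma(length(prof), shape = concentration * prof, rate = 1)
      pr <- if (all(g == 0)) prof else g / sum(g)
      cnt <- drop(stats::rmultinom(1, total_cells, pr))
      counts <- rbind(counts, cnt)
      subj_subtype <- c(subj_subtype, st)
    }
  }
  dimnames(counts) <- list(sprintf("subj%02d", seq_len(nrow(counts))),
                           regions)
  structure(list(counts = counts, subtype = subj_subtype,
                 region_names = regions),
            class = "input_count_matrix")
}

#' Default brain-region profiles for the input-count generator
#'
#' Fourteen regions spanning hippocampal and hypothalamic afferents; each
#' subtype profile shifts weight toward a different subset.
#'
#' @return named list of mean-proportion vectors.
#' @export
default_region_profiles <- function() {
  regions <- c("CA1", "CA2", "CA3", "ProS", "SuM", "VMH", "LPO",
               "LHA", "PH", "VMPO", "TU", "PeF", "MPO", "AHN")
  base <- c(18, 6, 12, 5, 8, 6, 5, 9, 7, 4, 3, 5, 6, 6)
  mk <- function(bump, where) {
    p <- base
    p[match(where, regions)] <- p[match(where, regions)] + bump
    setNames(p / sum(p), regions)
  }
  list(Glp1r = mk(14, c("CA1", "CA3")),
       Chat  = mk(14, c("SuM", "PH")),
       Foxp2 = mk(14, c("LHA", "PeF")),
       Calcr = mk(14, c("VMH", "AHN")))
}

gaussian_kernel <- function(sd_frames, support_frames = NULL) {
  if (is.null(support_frames)) {
    support_frames <- max(3L, 2L * ceiling(3 * sd_frames) + 1L)
  }
  h <- (support_frames - 1) / 2
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sd_frames^2))
  k / sum(k)
}

conv_same <- function(x, k) {
  n <- length(x); m <- length(k); h <- (m - 1) %/% 2
  # edge-renormalized centered convolution
  xp <- c(rep(NA, h), x, rep(NA, h))
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + m - 1)]
    ok <- !is.na(seg)
    out[i] <- sum(seg[ok] * k[ok]) / sum(k[ok])
  }
  out
}
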