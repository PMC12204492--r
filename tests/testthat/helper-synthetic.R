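# shared fixtures, all generated in code

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  r <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- r * c_ / choose(n, 2)
  (s - e) / ((r + c_) / 2 - e)
}

# single-motif configuration helper
one_motif_cfg <- function(weights, persistence = "transient", n_neurons = 1,
                          n_trials = 12, noise_sd = 0, p_success = 0.7,
                          seed = 1, ...) {
  m <- list(motifs = list(motif_spec("planted", weights, persistence)),
            proportions = 1)
  sim_config(n_neurons = n_neurons, n_trials = n_trials, noise_sd = noise_sd,
             baseline_drift_sd = 0, p_success = p_success, motifs = m,
             seed = seed, ...)
}

null_cohort_cfg <- function(n_neurons, n_trials = 30, seed = 1,
                            p_success = 0.7) {
  one_motif_cfg(c(cs_success = 0), n_neurons = n_neurons,
                n_trials = n_trials, noise_sd = 1, p_success = p_success,
                seed = seed)
}

cs_tensors <- function(session, window = c(-2, 3)) {
  tc <- build_trial_tensor(session, "cs_onset", window)
  list(S = tensor_by_outcome(tc, "success"),
       F = tensor_by_outcome(tc, "failure"),
       all = tc)
}

# hand-built white-noise trial tensor
noise_tensor <- function(n_neurons, n_trials, window = c(-2, 3), fr = 5,
                         data = NULL) {
  n_t <- round((window[2] - window[1]) * fr)
  if (is.null(data)) {
    data <- array(stats::rnorm(n_neurons * n_trials * n_t),
                  c(n_neurons, n_trials, n_t))
  }
  structure(list(data = data, align_event = "cs_onset", window_s = window,
                 outcome = rep("success", n_trials), frame_rate_hz = fr,
                 trial_index = seq_len(n_trials),
                 t_s = window[1] + (seq_len(n_t) - 0.5) / fr),
            class = "trial_tensor")
}
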