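#' Area under the ROC curve between two samples
#'
#' Rank-sum formulation with half credit for ties:
#' `P(response > baseline) + 0.5 * P(response == baseline)` over all
#' cross-pairs. 1 means every response value exceeds every baseline value
#' (activation), 0 the reverse (suppression), 0.5 indistinguishable.
#'
#' @param baseline,response numeric samples (nonempty).
#' @return scalar in `[0, 1]`.
#' @export
auroc <- function(baseline, response) {
  if (!length(baseline) || !length(response)) {
    stop("auroc: both samples must be nonempty")
  }
  n_b <- length(baseline)
  n_r <- length(response)
  r <- rank(c(baseline, response))
  u <- sum(r[(n_b + 1):(n_b + n_r)]) - n_r * (n_r + 1) / 2
  u / (n_b * n_r)
}

# pooled-sample auROC via binary search into the sorted baseline;
# identical to averaging per-timepoint auROCs when every timepoint
# contributes the same number of trials
auroc_pooled <- function(baseline_sorted, response) {
  n_b <- length(baseline_sorted)
  le <- findInterval(response, baseline_sorted)
  lt <- findInterval(response, baseline_sorted, left.open = TRUE)
  mean(lt + 0.5 * (le - lt)) / n_b
}

#' Analysis windows for each task variable
#'
#' CS, avoidance-run and shock variables use a 2-s baseline before the
#' event and a 2-s response after it; the pre-run variable uses baseline
#' 3-2 s before run onset and response in the final 2 s before it.
#'
#' @param variable "cs", "avrun", "pre_avrun" or "shock".
#' @return list with `align_event`, `baseline` and `response` windows (s)
#'   and the spanning tensor `window`.
#' @export
variable_windows <- function(variable) {
  switch(variable,
    cs = list(align_event = "cs_onset", baseline = c(-2, 0),
              response = c(0, 2), window = c(-2, 2)),
    avrun = list(align_event = "avrun_onset", baseline = c(-2, 0),
                 response = c(0, 2), window = c(-2, 2)),
    pre_avrun = list(align_event = "avrun_onset", baseline = c(-3, -2),
                     response = c(-2, 0), window = c(-3, 0)),
    shock = list(align_event = "shock_onset", baseline = c(-2, 0),
                 response = c(0, 2), window = c(-2, 2)),
    stop("unknown variable: ", variable))
}

tensor_window_cols <- function(tensor, win) {
  which(tensor$t_s >= win[1] & tensor$t_s < win[2])
}

#' Per-neuron auROC statistic for a task variable
#'
#' For each neuron the baseline distribution pools the baseline-window
#' values across trials; the auROC against the across-trial values at each
#' response-window timepoint is averaged over the window.
#'
#' @param tensor `trial_tensor` aligned to the variable's event and
#'   spanning both windows.
#' @param variable task variable name (see [variable_windows()]).
#' @param pool_baseline pool baseline values across trials (default) or
#'   average per-trial statistics.
#' @return numeric vector, one auROC per neuron.
#' @export
variable_auroc <- function(tensor, variable, pool_baseline = TRUE) {
  vw <- variable_windows(variable)
  if (dim(tensor$data)[2] < 2) stop("need at least 2 trials")
  b_cols <- tensor_window_cols(tensor, vw$baseline)
  r_cols <- tensor_window_cols(tensor, vw$response)
  if (!length(b_cols) || !length(r_cols)) {
    stop("tensor window does not cover the variable's windows")
  }
  n_neur <- dim(tensor$data)[1]
  vapply(seq_len(n_neur), function(i) {
    slab <- tensor$data[i, , , drop = FALSE]
    if (pool_baseline) {
      b <- as.numeric(slab[1, , b_cols])
      stats <- vapply(r_cols, function(cc) auroc(b, slab[1, , cc]),
                      numeric(1))
      mean(stats)
    } else {
      per_trial <- vapply(seq_len(dim(slab)[2]), function(tr) {
        b <- slab[1, tr, b_cols]
        mean(vapply(r_cols, function(cc) auroc(b, slab[1, tr, cc]),
                    numeric(1)))
      }, numeric(1))
      mean(per_trial)
    }
  }, numeric(1))
}

#' Classify neurons against a circular-permutation null
#'
#' For each permutation the whole z-scored session trace is circularly
#' shifted by one uniform random offset, the trial tensor is rebuilt at
#' the same trial times, and the auROC statistic recomputed. A neuron is
#' activated when its observed statistic exceeds the `1 - alpha/2`
#' percentile of its null, suppressed below the `alpha/2` percentile, else
#' unmodulated.
#'
#' @param session preprocessed `session_bundle`.
#' @param variable task variable name.
#' @param n_perm permutations (default 1000).
#' @param alpha two-sided significance level (0.05).
#' @param seed RNG seed.
#' @param exclude_fast_avoid_s fast-avoidance exclusion (s).
#' @return data.frame with `neuron_id`, `variable`, `auroc`, `null_lo`,
#'   `null_hi`, `class`.
#' @export
circular_null_classify <- function(session, variable, n_perm = 1000,
                                   alpha = 0.05, seed = 1L,
                                   exclude_fast_avoid_s = 4) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable null percentiles")
  vw <- variable_windows(variable)
  tensor <- build_trial_tensor(session, vw$align_event, vw$window,
                               exclude_fast_avoid_s = exclude_fast_avoid_s)
  z <- session$z
  n_frames <- ncol(z)
  n_neur <- nrow(z)
  fr <- session$frame_rate_hz
  n_t <- dim(tensor$data)[3]
  b_cols <- tensor_window_cols(tensor, vw$baseline)
  r_cols <- tensor_window_cols(tensor, vw$response)
  # absolute frame indices of the baseline/response samples per trial
  frame_idx <- outer(tensor$start_frames - 1L, seq_len(n_t) - 1L, `+`) + 1L
  b_idx <- as.integer(frame_idx[, b_cols])
  r_idx <- as.integer(frame_idx[, r_cols])
  obs <- variable_auroc(tensor, variable)
  set.seed(seed)
  offsets <- sample.int(n_frames - 1L, n_perm, replace = TRUE)
  null_mat <- matrix(NA_real_, n_neur, n_perm)
  for (p in seq_len(n_perm)) {
    off <- offsets[p]
    bi <- ((b_idx + off - 1L) %% n_frames) + 1L
    ri <- ((r_idx + off - 1L) %% n_frames) + 1L
    for (i in seq_len(n_neur)) {
      null_mat[i, p] <- auroc_pooled(sort(z[i, bi]), z[i, ri])
    }
  }
  lo <- apply(null_mat, 1, stats::quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(null_mat, 1, stats::quantile, probs = 1 - alpha / 2,
              names = FALSE)
  cls <- ifelse(obs > hi, "activated",
                ifelse(obs < lo, "suppressed", "unmodulated"))
  data.frame(neuron_id = session$neurons$neuron_id, variable = variable,
             auroc = obs, null_lo = lo, null_hi = hi, class = cls,
             stringsAsFactors = FALSE)
}

#' Fraction of neurons per modulation class
#'
#' @param results data.frame(s) from [circular_null_classify()].
#' @return data.frame of per-variable class fractions.
#' @export
modulation_summary <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(variable = r$variable[1],
               n = nrow(r),
               frac_activated = mean(r$class == "activated"),
               frac_suppressed = mean(r$class == "suppressed"),
               frac_unmodulated = mean(r$class == "unmodulated"))
  }))
}
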