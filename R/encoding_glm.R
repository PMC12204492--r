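#' Calcium-indicator impulse kernel
#'
#' Template impulse response used to convolve binary behavioral event trains
#' into fluorescence-like regressors: a linear rise from 0 to 1 over
#' `rise_s`, then exponential decay with time constant `decay_s`, truncated
#' at `duration_s`. The sampled vector is normalized so its peak is exactly 1.
#'
#' @param frame_rate_hz sampling rate of the trace the kernel will act on.
#' @param rise_s rise time (s).
#' @param decay_s decay time constant (s).
#' @param duration_s total kernel support (s).
#' @return numeric vector of length `round(duration_s * frame_rate_hz)`.
#' @export
gcamp_kernel <- function(frame_rate_hz, rise_s = 0.15, decay_s = 0.8,
                         duration_s = 1.5) {
  if (duration_s < rise_s) stop("duration_s must be >= rise_s")
  n <- round(duration_s * frame_rate_hz)
  if (n < 2) stop("kernel support must contain at least 2 samples")
  t <- (seq_len(n) - 1) / frame_rate_hz
  v <- ifelse(t <= rise_s,
              if (rise_s > 0) t / rise_s else 1,
              exp(-(t - rise_s) / decay_s))
  v / max(v)
}

#' Per-trial frame windows for encoding-model fitting
#'
#' @param events `event_table`.
#' @param frame_rate_hz trace sampling rate.
#' @param n_frames total frames in the session.
#' @param pre_s,post_s seconds before CS onset / after CS onset per trial.
#' @return list of integer frame-index vectors, one per trial (clipped to
#'   the recording).
#' @export
glm_trial_windows <- function(events, frame_rate_hz, n_frames,
                              pre_s = 2, post_s = 14) {
  lapply(seq_len(nrow(events)), function(i) {
    a <- floor((events$cs_onset_s[i] - pre_s) * frame_rate_hz) + 1L
    b <- floor((events$cs_onset_s[i] + post_s) * frame_rate_hz)
    seq.int(max(1L, a), min(n_frames, b))
  })
}

glm_event_frames <- function(events, frame_rate_hz) {
  succ <- events$outcome == "success"
  fr <- function(t) {
    t <- t[is.finite(t)]
    floor(t * frame_rate_hz) + 1L
  }
  list(cs_success = fr(events$cs_onset_s[succ]),
       cs_failure = fr(events$cs_onset_s[!succ]),
       shock = fr(events$shock_onset_s),
       avrun_onset = fr(events$avrun_onset_s),
       avrun_anticipatory = fr(events$avrun_onset_s))
}

convolve_events <- function(frames, kernel, n_frames) {
  x <- numeric(n_frames)
  frames <- frames[frames >= 1 & frames <= n_frames]
  x[frames] <- x[frames] + 1
  if (!length(frames)) return(x)
  # direct sparse convolution: one kernel copy per impulse, summed
  out <- numeric(n_frames)
  for (f in frames) {
    idx <- f:min(n_frames, f + length(kernel) - 1L)
    out[idx] <- out[idx] + kernel[seq_along(idx)]
  }
  out
}

shift_column <- function(x, shift_frames) {
  n <- length(x)
  if (shift_frames == 0) return(x)
  out <- numeric(n)
  if (shift_frames > 0) {              # forward: response lags the event
    out[(shift_frames + 1):n] <- x[1:(n - shift_frames)]
  } else {                             # backward: response precedes it
    k <- -shift_frames
    out[1:(n - k)] <- x[(k + 1):n]
  }
  out
}

#' Build a kernel-convolved, trial-concatenated design matrix
#'
#' Each behavioral predictor starts as a binary impulse train on the session
#' frame grid, is convolved with the indicator kernel, optionally shifted in
#' time (forward for cue/shock/run onsets, backward for the anticipatory
#' run regressor), sliced to the per-trial windows, and concatenated.
#' Predictors with no events are dropped (their coefficient would be
#' undefined). An intercept column is appended.
#'
#' @param events `event_table`.
#' @param frame_rate_hz trace sampling rate.
#' @param n_frames total session frames.
#' @param kernel impulse kernel; default [gcamp_kernel()] at `frame_rate_hz`.
#' @param shifts_s named numeric vector of per-predictor shifts in seconds
#'   (positive = forward). Defaults to 0 for all. Magnitudes are capped at
#'   `max_shift_s`.
#' @param max_shift_s cap on |shift| (2 s).
#' @param trial_windows list of frame-index vectors (default
#'   [glm_trial_windows()]); `NULL` keeps the full session as one segment.
#' @return list with `X` (rows = concatenated trial frames, named columns +
#'   `(intercept)`), `rows_per_trial` (list of row indices per trial),
#'   `frame_index` (session frame of each row), and `dropped` (predictors
#'   removed for having no events).
#' @export
build_design_matrix <- function(events, frame_rate_hz, n_frames,
                                kernel = gcamp_kernel(frame_rate_hz),
                                shifts_s = NULL, max_shift_s = 2,
                                trial_windows = glm_trial_windows(
                                  events, frame_rate_hz, n_frames)) {
  ev <- glm_event_frames(events, frame_rate_hz)
  preds <- names(ev)
  backward <- c(avrun_anticipatory = TRUE)
  if (is.null(shifts_s)) {
    # the anticipatory regressor must lead the run onset, otherwise it is
    # collinear with the onset column; 1 s lead by default
    shifts_s <- setNames(numeric(length(preds)), preds)
    shifts_s["avrun_anticipatory"] <- -1
  }
  cols <- list()
  dropped <- character()
  for (p in preds) {
    if (!length(ev[[p]])) { dropped <- c(dropped, p); next }
    s <- if (p %in% names(shifts_s)) shifts_s[[p]] else 0
    s <- sign(s) * min(abs(s), max_shift_s)
    if (isTRUE(backward[p]) && s > 0) s <- -s
    x <- convolve_events(ev[[p]], kernel, n_frames)
    cols[[p]] <- shift_column(x, round(s * frame_rate_hz))
  }
  if (length(dropped)) {
    message("design matrix: dropped zero-event predictors: ",
            paste(dropped, collapse = ", "))
  }
  if (is.null(trial_windows)) trial_windows <- list(seq_len(n_frames))
  frame_index <- unlist(trial_windows, use.names = FALSE)
  X <- vapply(cols, function(x) x[frame_index], numeric(length(frame_index)))
  X <- cbind(X, `(intercept)` = 1)
  off <- 0L
  rows_per_trial <- lapply(trial_windows, function(w) {
    r <- off + seq_along(w); off <<- off + length(w); r
  })
  list(X = X, rows_per_trial = rows_per_trial, frame_index = frame_index,
       dropped = dropped)
}

#' Fit the encoding model by ordinary least squares
#'
#' @param design design list from [build_design_matrix()], or a bare matrix.
#' @param trace numeric vector of the (concatenated) fluorescence trace,
#'   same length as `nrow(X)`.
#' @return list of class `glm_fit` with `betas` (named, excluding the
#'   intercept), `intercept`, `r2_full`, `fitted`, `residuals`, `sse`, `sst`.
#' @export
fit_glm <- function(design, trace) {
  X <- if (is.list(design) && !is.null(design$X)) design$X else as.matrix(design)
  trace <- as.numeric(trace)
  if (nrow(X) != length(trace)) stop("design/trace length mismatch")
  if (!all(is.finite(trace))) stop("trace must be finite")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, trace)
  fitted <- drop(X %*% beta)
  res <- trace - fitted
  sst <- sum((trace - mean(trace))^2)
  sse <- sum(res^2)
  ic <- which(names(beta) == "(intercept)")
  structure(list(betas = beta[-ic], intercept = unname(beta[ic]),
                 coef = beta, r2_full = 1 - sse / sst,
                 fitted = fitted, residuals = res, sse = sse, sst = sst),
            class = "glm_fit")
}

#' Leave-one-trial-out cross-validation of the encoding model
#'
#' Each trial is held out in turn; the model is refit on the remaining
#' trials and predicts the held-out segment. `r2_cv` compares the
#' concatenated out-of-fold predictions with the observations.
#'
#' @param design design list from [build_design_matrix()] (needs
#'   `rows_per_trial`).
#' @param trace concatenated trace, length `nrow(design$X)`.
#' @return list with `r2_cv`, `mse_cv` (mean over folds), `mse_per_fold`,
#'   `predictions` (list per trial).
#' @export
loo_cv <- function(design, trace) {
  rows <- design$rows_per_trial
  n_tr <- length(rows)
  if (n_tr < 3) stop("leave-one-out CV needs at least 3 trials")
  X <- design$X
  if (n_tr <= ncol(X)) {
    warning("fewer trials than predictors; CV folds may be unstable")
  }
  preds <- vector("list", n_tr)
  mse <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    hold <- rows[[i]]
    keep <- unlist(rows[-i], use.names = FALSE)
    beta <- qr.coef(qr(X[keep, , drop = FALSE]), trace[keep])
    beta[is.na(beta)] <- 0
    preds[[i]] <- drop(X[hold, , drop = FALSE] %*% beta)
    mse[i] <- mean((trace[hold] - preds[[i]])^2)
  }
  yhat <- unlist(preds, use.names = FALSE)
  y <- trace[unlist(rows, use.names = FALSE)]
  r2_cv <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(r2_cv = r2_cv, mse_cv = mean(mse), mse_per_fold = mse,
       predictions = preds)
}

#' Contribution of one predictor by zeroed-column nested comparison
#'
#' The predictor's column is zeroed about its mean in the design while
#' keeping the fitted coefficients (no refit); the drop in R^2 relative
#' to the full model gives the relative contribution, and the nested
#' sum-of-squares comparison gives an F statistic. Zeroing the centered
#' column (rather than the raw one) leaves the model's mean prediction
#' intact, so a sole informative predictor contributes exactly 100%.
#'
#' @param fit a `glm_fit`.
#' @param design the design used to fit it.
#' @param trace the trace it was fit on.
#' @param predictor column name to zero.
#' @return list with `relative_drop_pct`, `f_stat`, `r2_zeroed`.
#' @export
predictor_contribution <- function(fit, design, trace, predictor) {
  X <- if (is.list(design) && !is.null(design$X)) design$X else as.matrix(design)
  if (!predictor %in% colnames(X)) stop("unknown predictor: ", predictor)
  if (fit$r2_full <= 0) {
    return(list(relative_drop_pct = NA_real_, f_stat = NA_real_,
                r2_zeroed = NA_real_, undefined = TRUE))
  }
  xp <- X[, predictor]
  fitted_z <- fit$fitted - fit$coef[[predictor]] * (xp - mean(xp))
  sse_z <- sum((trace - fitted_z)^2)
  r2_z <- 1 - sse_z / fit$sst
  q <- 1L
  n <- nrow(X); p <- ncol(X)
  f_stat <- ((sse_z - fit$sse) / q) / (fit$sse / (n - p))
  list(relative_drop_pct = 100 * (fit$r2_full - r2_z) / fit$r2_full,
       f_stat = f_stat, r2_zeroed = r2_z, undefined = FALSE)
}

#' Fit the encoding model for every neuron in a session
#'
#' @param session `session_bundle`; by default the raw `traces` rows are
#'   used (synthetic sessions carry signal-unit traces), set `use_z = TRUE`
#'   to fit the z-scored traces from [preprocess_session()].
#' @param shifts_s,optimize_shifts fixed per-predictor shifts, or grid
#'   optimization of each predictor's shift (0 to `max_shift_s` at frame
#'   resolution, backward for the anticipatory regressor) by training R^2.
#' @param max_shift_s shift cap in seconds.
#' @return data.frame, one row per neuron, with beta columns (`b_<pred>`),
#'   `r2_full`, `r2_cv`, `mse_cv` and contribution columns
#'   (`drop_<pred>`, `f_<pred>`).
#' @export
fit_session_glms <- function(session, shifts_s = NULL,
                             optimize_shifts = FALSE, max_shift_s = 2,
                             use_z = FALSE) {
  tr_mat <- if (use_z) {
    if (is.null(session$z)) stop("run preprocess_session() first")
    session$z
  } else session$traces
  n_frames <- ncol(tr_mat)
  fr <- session$frame_rate_hz
  base_design <- build_design_matrix(session$events, fr, n_frames,
                                     shifts_s = shifts_s,
                                     max_shift_s = max_shift_s)
  preds <- setdiff(colnames(base_design$X), "(intercept)")
  rows <- lapply(seq_len(nrow(tr_mat)), function(i) {
    y <- tr_mat[i, base_design$frame_index]
    design <- base_design
    if (optimize_shifts) {
      design <- optimize_design_shifts(session$events, fr, n_frames, y,
                                       max_shift_s)
    }
    fit <- fit_glm(design, y)
    cv <- loo_cv(design, y)
    out <- c(setNames(as.list(fit$betas[preds]), paste0("b_", preds)),
             list(r2_full = fit$r2_full, r2_cv = cv$r2_cv,
                  mse_cv = cv$mse_cv))
    for (p in preds) {
      ctb <- predictor_contribution(fit, design, y, p)
      out[[paste0("drop_", p)]] <- ctb$relative_drop_pct
      out[[paste0("f_", p)]] <- ctb$f_stat
    }
    as.data.frame(out)
  })
  res <- do.call(rbind, rows)
  cbind(neuron_id = session$neurons$neuron_id, res,
        stringsAsFactors = FALSE)
}

optimize_design_shifts <- function(events, fr, n_frames, y, max_shift_s) {
  shift_grid <- seq(0, max_shift_s, by = 1 / fr)
  ev <- glm_event_frames(events, fr)
  preds <- names(ev)[vapply(ev, length, 1L) > 0]
  shifts <- setNames(numeric(length(preds)), preds)
  for (p in preds) {
    r2s <- vapply(shift_grid, function(s) {
      sh <- shifts
      sh[p] <- if (p == "avrun_anticipatory") -s else s
      d <- build_design_matrix(events, fr, n_frames, shifts_s = sh,
                               max_shift_s = max_shift_s)
      fit_glm(d, y)$r2_full
    }, numeric(1))
    s_best <- shift_grid[which.max(r2s)]
    shifts[p] <- if (p == "avrun_anticipatory") -s_best else s_best
  }
  build_design_matrix(events, fr, n_frames, shifts_s = shifts,
                      max_shift_s = max_shift_s)
}

#' Cue-outcome and action indices from per-unit encoding fits
#'
#' `cue_outcome` is the CS-success beta minus the CS-failure beta;
#' `action` is the sum of the anticipatory and onset avoidance-run betas.
#' Group summaries report mean, SEM and one-sample t / Wilcoxon tests
#' against zero.
#'
#' @param fits data.frame from [fit_session_glms()] (or the photometry
#'   equivalent), with beta columns `b_cs_success`, `b_cs_failure`,
#'   `b_avrun_anticipatory`, `b_avrun_onset`.
#' @param group optional grouping vector (subtype or afferent region).
#' @return list with `per_unit` (indices per row) and `summary` (per group).
#' @export
derived_indices <- function(fits, group = NULL) {
  need <- c("b_cs_success", "b_cs_failure")
  have_cue <- all(need %in% names(fits))
  have_act <- all(c("b_avrun_anticipatory", "b_avrun_onset") %in% names(fits))
  per <- data.frame(row = seq_len(nrow(fits)))
  if ("neuron_id" %in% names(fits)) per$neuron_id <- fits$neuron_id
  per$cue_outcome <- if (have_cue) fits$b_cs_success - fits$b_cs_failure else NA_real_
  per$action <- if (have_act) {
    fits$b_avrun_anticipatory + fits$b_avrun_onset
  } else NA_real_
  if (is.null(group)) group <- rep("all", nrow(fits))
  per$group <- group
  summ <- do.call(rbind, lapply(split(per, per$group), function(d) {
    one <- function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2) {
        return(c(mean = mean(x), sem = NA, p_t = NA, p_wilcox = NA))
      }
      c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
        p_t = stats::t.test(x)$p.value,
        p_wilcox = stats::wilcox.test(x, exact = FALSE)$p.value)
    }
    co <- one(d$cue_outcome); ac <- one(d$action)
    data.frame(group = d$group[1], n = nrow(d),
               cue_outcome_mean = co["mean"], cue_outcome_sem = co["sem"],
               cue_outcome_p_t = co["p_t"], cue_outcome_p_wilcox = co["p_wilcox"],
               action_mean = ac["mean"], action_sem = ac["sem"],
               action_p_t = ac["p_t"], action_p_wilcox = ac["p_wilcox"],
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(per_unit = per, summary = summ)
}
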