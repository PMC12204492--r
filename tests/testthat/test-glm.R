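test_that("indicator kernel has the documented shape", {
  k20 <- gcamp_kernel(20)
  expect_length(k20, 30)                       # 1.5 s at 20 Hz
  t <- (seq_along(k20) - 1) / 20
  expect_equal(k20[t == 0.15], 1)              # peak at the rise time
  expect_equal(k20[t == 0.95], exp(-1))        # one decay constant later
  expect_true(all(k20 >= 0) && max(k20) == 1)
  expect_error(gcamp_kernel(20, rise_s = 2, duration_s = 1.5), "rise")
})

test_that("design columns are kernel copies at events, shifted and summed", {
  fr <- 20
  ev <- event_table(1:2, c(5, 40), c(11, 50), c("success", "failure"),
                    shock_onset_s = c(NA, 50), avrun_onset_s = c(11, 51))
  n_frames <- 60 * fr
  d <- build_design_matrix(ev, fr, n_frames, trial_windows = NULL)
  kern <- gcamp_kernel(fr)
  # single success-cue impulse: the column is the kernel placed at 5 s
  col <- d$X[, "cs_success"]
  f0 <- floor(5 * fr) + 1
  expect_equal(col[f0:(f0 + 29)], kern)
  expect_true(all(col[-(f0:(f0 + 29))] == 0))
  # forward shift by 0.5 s delays the column by 10 samples
  d2 <- build_design_matrix(ev, fr, n_frames,
                            shifts_s = c(cs_success = 0.5),
                            trial_windows = NULL)
  expect_equal(d2$X[11:n_frames, "cs_success"], col[1:(n_frames - 10)])
  # two overlapping events sum their kernel copies
  ev3 <- event_table(1:2, c(5, 5.5), c(11, 11.5), c("success", "success"),
                     avrun_onset_s = c(11, 11.5))
  d3 <- build_design_matrix(ev3, fr, n_frames, trial_windows = NULL)
  one <- numeric(n_frames); two <- numeric(n_frames)
  one[f0:(f0 + 29)] <- kern
  f1 <- floor(5.5 * fr) + 1
  two[f1:(f1 + 29)] <- kern
  expect_equal(d3$X[, "cs_success"], one + two)
  # zero-event predictors are dropped with a message
  expect_message(build_design_matrix(ev3, fr, n_frames,
                                     trial_windows = NULL),
                 "shock")
})

test_that("OLS fit recovers planted coefficients exactly", {
  fr <- 5
  ev <- event_table(1:4, c(10, 50, 90, 130), c(16, 60, 96, 140),
                    c("success", "failure", "success", "failure"),
                    shock_onset_s = c(NA, 60, NA, 140),
                    avrun_onset_s = c(16, 61, 96, 141))
  n_frames <- 160 * fr
  d <- build_design_matrix(ev, fr, n_frames)
  y <- 2 * d$X[, "cs_success"] + 0 * d$X[, "cs_failure"]
  fit <- fit_glm(d, y)
  expect_equal(unname(fit$betas["cs_success"]), 2, tolerance = 1e-10)
  expect_equal(fit$r2_full, 1, tolerance = 1e-10)
  # residuals orthogonal to the design
  set.seed(1)
  y2 <- d$X %*% rnorm(ncol(d$X)) + rnorm(nrow(d$X))
  fit2 <- fit_glm(d, y2)
  expect_lt(max(abs(crossprod(d$X, fit2$residuals))), 1e-8)
  # pure-noise trace: betas near zero, r2 near zero
  # pure noise with few events per predictor: betas are noisy but the
  # model explains almost nothing
  set.seed(2)
  fitn <- fit_glm(d, rnorm(nrow(d$X)))
  expect_lt(max(abs(fitn$betas)), 1.5)
  expect_lt(fitn$r2_full, 0.1)
  # collinear columns are named in the error
  Xbad <- cbind(a = d$X[, 1], b = d$X[, 1], `(intercept)` = 1)
  expect_error(fit_glm(Xbad, y2), "collinear")
})

test_that("leave-one-trial-out CV behaves on planted and null traces", {
  fr <- 5
  on <- 10 + (0:5) * 40
  ev <- event_table(1:6, on, on + 6, rep(c("success", "failure"), 3),
                    shock_onset_s = ifelse(1:6 %% 2 == 0, on + 10, NA),
                    avrun_onset_s = on + 6)
  n_frames <- (max(on) + 30) * fr
  d <- build_design_matrix(ev, fr, n_frames)
  beta <- c(1.5, -1, 2, 0.5, 0.3)
  y <- drop(d$X %*% c(beta, 0))
  # 6 trials against 6 columns: folds are flagged as potentially unstable
  expect_warning(cv <- loo_cv(d, y), "unstable")
  expect_equal(length(cv$mse_per_fold), 6)      # one fold per trial
  expect_gt(cv$r2_cv, 0.999)
  # null trace: cross-validated r2 is not positive on average
  set.seed(3)
  r2s <- replicate(10,
                   suppressWarnings(loo_cv(d, rnorm(nrow(d$X)))$r2_cv))
  expect_lt(mean(r2s), 0.05)
  expect_error(loo_cv(list(X = d$X, rows_per_trial = d$rows_per_trial[1:2]),
                      y), "3 trials")
})

test_that("zeroed-predictor contributions partition explained variance", {
  set.seed(4)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  x1 <- x1 - mean(x1)
  x2 <- x2 - mean(x2)
  x2 <- x2 - x1 * sum(x1 * x2) / sum(x1^2)     # orthogonalize, centered
  x1 <- x1 / sd(x1); x2 <- x2 / sd(x2)
  X <- cbind(a = x1, b = x2, `(intercept)` = 1)
  y <- x1 + x2
  fit <- fit_glm(X, y)
  ca <- predictor_contribution(fit, X, y, "a")
  cb <- predictor_contribution(fit, X, y, "b")
  expect_equal(ca$relative_drop_pct, 50, tolerance = 2)
  expect_equal(cb$relative_drop_pct, 50, tolerance = 2)
  # sole informative predictor: 100% drop; uninformative: ~0
  y1 <- 2 * x1
  f1 <- fit_glm(X, y1)
  expect_equal(predictor_contribution(f1, X, y1, "a")$relative_drop_pct,
               100, tolerance = 1e-6)
  expect_equal(predictor_contribution(f1, X, y1, "b")$relative_drop_pct,
               0, tolerance = 1e-6)
  expect_true(predictor_contribution(f1, X, y1, "a")$f_stat >
                predictor_contribution(f1, X, y1, "b")$f_stat)
})

test_that("session-level fits recover transient motif amplitudes", {
  mot <- list(motifs = list(
    motif_spec("a", c(cs_success = 1.2, shock = 2)),
    motif_spec("b", c(avrun_onset = 1.5, avrun_anticipatory = 0.8))),
    proportions = c(0.5, 0.5))
  cfg <- sim_config(n_neurons = 6, n_trials = 14, noise_sd = 0,
                    baseline_drift_sd = 0, motifs = mot, seed = 5)
  s <- generate_session(cfg)
  fits <- fit_session_glms(s)
  amps <- s$ground_truth$amplitudes
  for (p in c("cs_success", "cs_failure", "shock", "avrun_onset",
              "avrun_anticipatory")) {
    expect_equal(unname(fits[[paste0("b_", p)]]), unname(amps[, p]),
                 tolerance = 1e-6)
  }
  expect_true(all(fits$r2_cv > 0.999))
})

test_that("derived indices combine betas and summarize groups", {
  fits <- data.frame(neuron_id = c("a", "b", "c"),
                     b_cs_success = c(1, 0.5, 2),
                     b_cs_failure = c(1, 0.2, 0.5),
                     b_avrun_anticipatory = c(0.3, 0, 1),
                     b_avrun_onset = c(0.2, 0, -0.5))
  di <- derived_indices(fits)
  expect_equal(di$per_unit$cue_outcome, c(0, 0.3, 1.5))
  expect_equal(di$per_unit$action, c(0.5, 0, 0.5))
  expect_equal(di$summary$n, 3)
  expect_true(all(c("cue_outcome_p_t", "action_p_wilcox") %in%
                    names(di$summary)))
})

test_that("photometry and single-neuron encoding paths agree", {
  cfg <- sim_config(n_trials = 10, seed = 6)
  ph <- generate_photometry(cfg, c(cs_success = 1.5, cs_failure = 0.5),
                            artifact_sd = 0.3)
  f1 <- fit_photometry_glm(ph)
  s <- photometry_as_session(ph)
  f2 <- fit_session_glms(s)
  expect_equal(f1, f2)
  # planted success > failure weight: positive cue-outcome index
  expect_gt(f1$b_cs_success - f1$b_cs_failure, 0)
})
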