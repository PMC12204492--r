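test_that("neuropil correction is elementwise F - r * F_neu", {
  expect_equal(neuropil_correct(10, 0), 10)
  expect_equal(neuropil_correct(10, 10, r = 0.7), 3.0)
  set.seed(1)
  F <- matrix(runif(15, 1, 5), 3)
  Fn <- matrix(runif(15, 0, 1), 3)
  oracle <- F
  for (i in 1:3) for (j in 1:5) oracle[i, j] <- F[i, j] - 0.7 * Fn[i, j]
  expect_equal(neuropil_correct(F, Fn), oracle)
  expect_error(neuropil_correct(F, Fn[, 1:3]), "shape")
  expect_error(neuropil_correct(1, 1, r = 1.5), "\\[0, 1\\]")
})

test_that("sliding-percentile dF/F matches hand and brute-force oracles", {
  # constant trace: F0 = c everywhere, dF/F = 0
  expect_equal(sliding_dff(rep(3, 50), 1, window_s = 5), rep(0, 50))
  # 10th percentile of {1,1,1,1,11} under linear interpolation is 1
  tr <- c(1, 1, 1, 1, 11)
  expect_equal(sliding_dff(c(tr, 1), 1, window_s = 5)[5], 10)
  # brute-force per-frame percentile loop on a stepped trace
  set.seed(2)
  tr <- 2 + abs(rnorm(80)) + rep(c(0, 3), each = 40)
  got <- sliding_dff(tr, frame_rate_hz = 2, window_s = 10, pct = 10)
  w <- round(10 * 2); half <- w %/% 2
  oracle <- vapply(seq_along(tr), function(i) {
    win <- tr[max(1, i - half):min(length(tr), i + half)]
    f0 <- unname(quantile(win, 0.1))
    (tr[i] - f0) / f0
  }, numeric(1))
  expect_equal(got, oracle)
  # scale invariance of dF/F
  expect_equal(sliding_dff(5 * tr, 2, 10), got)
  expect_error(sliding_dff(tr - 5, 2, 10), "frame")
})

test_that("session normalization z-scores after splicing and interpolation", {
  set.seed(3)
  parts <- list(rnorm(40, 5), rnorm(25, 5), rnorm(35, 5))
  z <- normalize_session(parts)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  x <- unlist(parts)
  expect_equal(z, (x - mean(x)) / sd(x))
  # masked frames on a linear ramp are reconstructed by interpolation
  ramp <- seq(0, 10, length.out = 21)
  mask <- seq_along(ramp) %in% 5:7
  zr <- normalize_session(ramp, mask)
  expect_equal(zr, (ramp - mean(ramp)) / sd(ramp), tolerance = 1e-10)
  expect_error(normalize_session(rep(1, 10)), "variance")
  expect_error(normalize_session(ramp, rep(TRUE, 21)), "masked")
})

test_that("isosbestic regression removes the reference channel", {
  set.seed(4)
  x <- 10 + cumsum(rnorm(600, 0, 0.05))
  expect_lt(max(abs(isosbestic_correct(x, x, smooth_sd_s = 0))), 1e-8)
  expect_lt(max(abs(isosbestic_correct(2 * x + 3, x, smooth_sd_s = 0))),
            1e-8)
  expect_error(isosbestic_correct(x, rep(5, 600), smooth_sd_s = 0),
               "degenerate")
  # synthetic signal + artifact: artifact variance reduced >= 90%
  cfg <- sim_config(n_trials = 8, seed = 5)
  ph <- generate_photometry(cfg, c(cs_success = 1.5), artifact_sd = 0.6,
                            noise_sd = 0.02)
  off <- 10 - min(ph$sig465, ph$sig405)
  z <- isosbestic_correct(ph$sig465 + off, ph$sig405 + off, rate_hz = 30)
  raw_pct <- 100 * (ph$sig465 + off) / off
  fit_raw <- lm(raw_pct ~ ph$ground_truth$artifact)
  fit_cor <- lm(z ~ ph$ground_truth$artifact)
  var_explained <- function(f) summary(f)$r.squared * var(f$model[[1]])
  expect_lt(var_explained(fit_cor), 0.1 * var_explained(fit_raw))
})

test_that("kinematics recovers speed, run onsets, freezing and flight", {
  # stationary track: zero speed, one session-long freezing bout, no flight
  still <- behavior_track(matrix(5, 300, 2))
  k <- kinematics(still)
  expect_true(all(k$speed < 1e-10))
  expect_equal(nrow(k$freezing_bouts), 1)
  expect_length(k$flight_frames, 0)
  # constant velocity 10 cm/s: speed within 2% away from edges
  t <- seq(0, 10, by = 1 / 30)
  cv <- behavior_track(cbind(5 + 10 * t, rep(5, length(t))))
  ks <- kinematics(cv)
  mid <- 31:(length(t) - 31)
  expect_true(all(abs(ks$speed[mid] - 10) < 0.2))
  # planted run onsets recovered within one video frame
  s <- generate_session(sim_config(n_trials = 8, seed = 8))
  kin <- kinematics(s$behavior, s$events)
  err <- abs(kin$avrun_onsets_s - s$events$avrun_onset_s)
  expect_true(all(err <= 1 / 30 + 1e-9))
  expect_error(kinematics(behavior_track(matrix(0, 10, 2))), "short")
})

test_that("trial tensors enforce the fast-avoidance exclusion and windows", {
  # 10 trials, 2 with latency 3 s -> 8 survive
  lat <- c(rep(6, 8), 3, 3)
  on <- 20 + (0:9) * 40
  ev <- event_table(1:10, on, on + lat, rep("success", 10),
                    avrun_onset_s = on + lat)
  b <- session_bundle(matrix(rnorm(2 * 2200), 2), 5, ev)
  b$z <- b$traces
  tt <- build_trial_tensor(b, "cs_onset", c(-2, 3))
  expect_equal(dim(tt$data)[2], 8)
  # window arithmetic: (-2, 3) at 5 Hz -> 25 timepoints
  expect_equal(dim(tt$data)[3], 25)
  # half-open window edges
  expect_equal(tt$t_s[1], -1.9)
  expect_equal(tt$t_s[25], 2.9)
  # alignment to avrun on trials lacking a run: excluded
  ev2 <- ev
  ev2$avrun_onset_s[1:3] <- NA
  b2 <- session_bundle(matrix(rnorm(2 * 2200), 2), 5, ev2)
  b2$z <- b2$traces
  t2 <- build_trial_tensor(b2, "avrun_onset", c(-2, 2))
  expect_equal(dim(t2$data)[2], 5)
  expect_error(build_trial_tensor(b2, "shock_onset", c(-2, 2)),
               "no trials")
})

test_that("preprocessed sessions have unit-variance zero-mean traces", {
  s <- preprocess_session(generate_session(sim_config(n_neurons = 4,
                                                      n_trials = 6,
                                                      seed = 2)))
  expect_equal(unname(rowMeans(s$z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(s$z, 1, sd)), rep(1, 4), tolerance = 1e-10)
})
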