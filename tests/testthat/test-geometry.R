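test_that("trial-averaged PCA captures a planted rank-1 structure", {
  set.seed(1)
  n <- 20; n_tr <- 6; n_t <- 25
  pattern <- sin(seq(0, pi, length.out = n_t))
  load <- rep(c(1, -1), each = n / 2)          # two anti-correlated groups
  mk <- function() {
    d <- array(0, c(n, n_tr, n_t))
    for (tr in seq_len(n_tr)) {
      d[, tr, ] <- outer(load, pattern) + rnorm(n * n_t, 0, 0.01)
    }
    noise_tensor(n, n_tr, data = d)
  }
  emb <- trial_averaged_pca(mk(), mk())
  expect_gt(emb$explained_variance_ratio[1], 0.95)
  # PCA properties on any input
  expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-9)
  expect_equal(unname(colSums(emb$components^2)),
               rep(1, ncol(emb$components)))
})

test_that("identical condition means collapse the concatenated halves", {
  set.seed(2)
  tS <- noise_tensor(10, 4)
  tF <- tS
  emb <- trial_averaged_pca(tS, tF)
  nt <- emb$n_time
  expect_equal(emb$concat_means[, 1:nt], emb$concat_means[, nt + 1:nt])
})

test_that("projection of the trial-averaged data recovers the PCA scores", {
  set.seed(3)
  tS <- noise_tensor(12, 5)
  tF <- noise_tensor(12, 5)
  emb <- trial_averaged_pca(tS, tF)
  k <- 3
  avg <- apply(tS$data, c(1, 3), mean)
  tAvg <- tS
  tAvg$data <- array(avg, c(12, 1, dim(tS$data)[3]))
  pr <- project_single_trials(emb, tAvg, n_pcs = k)
  expect_equal(pr[1, , ],
               unname(t(emb$scores[seq_len(emb$n_time), 1:k])),
               tolerance = 1e-10)
  expect_error(project_single_trials(emb, noise_tensor(5, 2)), "mismatch")
})

test_that("module Mahalanobis distance equals the direct solve", {
  set.seed(4)
  for (rep_ in 1:100) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(20 * p), 20)
    S <- crossprod(matrix(rnorm(3 * p * p), 3 * p)) / (3 * p)
    a <- rnorm(p); b <- rnorm(p)
    d <- a - b
    oracle <- sqrt(drop(t(d) %*% solve(S) %*% d))
    expect_equal(mahalanobis_dist(a, b, S), oracle, tolerance = 1e-8)
  }
  # identity covariance reduces to Euclidean distance
  a <- c(1, 2, 3); b <- c(0, 0, 1)
  expect_equal(mahalanobis_dist(a, b, diag(3)), sqrt(sum((a - b)^2)))
})

test_that("trajectory divergence flags planted post-event separation only", {
  set.seed(5)
  n <- 40; n_tr <- 12; n_t <- 25
  t_s <- seq(-1.9, 2.9, by = 0.2)
  bump <- pmax(0, pmin((t_s - 0) / 0.4, 1))     # diverges after t = 0
  mkc <- function(sign_) {
    d <- array(rnorm(n * n_tr * n_t, 0, 0.4), c(n, n_tr, n_t))
    for (tr in seq_len(n_tr)) {
      d[, tr, ] <- d[, tr, ] + sign_ * outer(rep(1, n), bump)
    }
    noise_tensor(n, n_tr, data = d)
  }
  div <- trajectory_divergence(mkc(1), mkc(-1), n_boot = 25,
                               baseline_window = c(-2, 0), seed = 1)
  expect_true(all(div$significant[div$t_s > 0.5]))
  expect_false(any(div$significant[div$t_s < 0]))
  # identical tensors: no significance, distances flat
  same <- mkc(0)
  div0 <- trajectory_divergence(same, same, n_boot = 10,
                                baseline_window = c(-2, 0), seed = 2)
  expect_false(any(div0$significant))
})

test_that("coding direction follows the hand-computed difference vector", {
  n_t <- 25
  mk2 <- function(mu) {
    d <- array(0, c(2, 3, n_t))
    d[1, , ] <- mu[1]; d[2, , ] <- mu[2]
    noise_tensor(2, 3, data = d)
  }
  cd <- coding_direction(mk2(c(1, 0)), mk2(c(0, 1)), window_s = c(0, 3))
  expect_equal(cd$cd, c(1, -1) / sqrt(2))
  expect_equal(sqrt(sum(cd$cd^2)), 1, tolerance = 1e-12)
  # identical tensors: zero-vector flag, all projections zero
  cd0 <- coding_direction(mk2(c(1, 1)), mk2(c(1, 1)))
  expect_true(cd0$zero_flag)
  expect_true(all(cd0$projections_success == 0))
})

test_that("CD projections separate conditions by construction on any cohort", {
  s <- preprocess_session(generate_session(sim_config(n_neurons = 30,
                                                      n_trials = 20,
                                                      seed = 6)))
  ts_ <- cs_tensors(s)
  cd <- coding_direction(ts_$S, ts_$F, window_s = c(0, 3))
  w <- which(ts_$S$t_s >= 0 & ts_$S$t_s < 3)
  expect_gt(mean(cd$projections_success[, w]), 0)
  expect_lt(mean(cd$projections_failure[, w]), 0)
  # neuron-permutation invariance
  perm <- sample(dim(ts_$S$data)[1])
  tSp <- ts_$S; tSp$data <- tSp$data[perm, , , drop = FALSE]
  tFp <- ts_$F; tFp$data <- tFp$data[perm, , , drop = FALSE]
  cdp <- coding_direction(tSp, tFp, window_s = c(0, 3))
  expect_equal(cdp$projections_success, cd$projections_success,
               tolerance = 1e-10)
  expect_equal(cdp$cd, cd$cd[perm], tolerance = 1e-10)
})

test_that("residual PCs are orthogonal to the CD and recover a planted second factor", {
  set.seed(7)
  n <- 30; n_tr <- 8; n_t <- 25
  outcome_axis <- rnorm(n); outcome_axis <- outcome_axis / sqrt(sum(outcome_axis^2))
  time_axis <- rnorm(n); time_axis <- time_axis - outcome_axis * sum(time_axis * outcome_axis)
  time_axis <- time_axis / sqrt(sum(time_axis^2))
  t_s <- seq(-1.9, 2.9, by = 0.2)
  ramp <- (t_s - min(t_s)) / diff(range(t_s))
  step <- as.numeric(t_s > 0)
  mkf <- function(sgn) {
    d <- array(rnorm(n * n_tr * n_t, 0, 0.02), c(n, n_tr, n_t))
    for (tr in seq_len(n_tr)) {
      d[, tr, ] <- d[, tr, ] + sgn * outer(outcome_axis, step) +
        3 * outer(time_axis, ramp)
    }
    noise_tensor(n, n_tr, data = d)
  }
  tS <- mkf(1); tF <- mkf(-1)
  cd <- coding_direction(tS, tF, window_s = c(0, 3))
  rp <- residual_pcs(cd, tS, tF)
  expect_lt(max(abs(t(rp$components) %*% cd$cd)), 1e-8)
  expect_gt(abs(sum(rp$components[, 1] * time_axis)), 0.95)
  # rank-1 data along the cd leaves ~no residual variance
  mk1 <- function(sgn) {
    d <- array(0, c(n, n_tr, n_t))
    for (tr in seq_len(n_tr)) d[, tr, ] <- sgn * outer(outcome_axis, step)
    noise_tensor(n, n_tr, data = d)
  }
  cd1 <- coding_direction(mk1(1), mk1(-1), window_s = c(0, 3))
  rp1 <- residual_pcs(cd1, mk1(1), mk1(-1))
  expect_lt(rp1$residual_total_variance, 1e-16 * n * n_t)
})
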