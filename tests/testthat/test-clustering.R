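test_that("epoch features concatenate the four trial-averaged windows", {
  set.seed(1)
  tens <- list(cs_success = noise_tensor(6, 4), cs_failure = noise_tensor(6, 4),
               shock = noise_tensor(6, 4, window = c(-2, 2)),
               avrun = noise_tensor(6, 4, window = c(-2, 2)))
  f <- epoch_feature_matrix(tens)
  expect_equal(dim(f), c(6, 25 + 25 + 20 + 20))
  # row i is the concatenation of neuron i's four epoch means
  expect_equal(f[3, 1:25], apply(tens$cs_success$data, c(1, 3), mean)[3, ])
  # zero-activity neuron gives a zero row
  tens0 <- lapply(tens, function(t) { t$data[2, , ] <- 0; t })
  expect_true(all(epoch_feature_matrix(tens0)[2, ] == 0))
  expect_error(epoch_feature_matrix(tens[1:3]), "missing epochs")
})

test_that("clustering recovers well-separated planted motifs and picks their k", {
  set.seed(2)
  centers <- matrix(rnorm(3 * 40, sd = 4), 3)
  truth <- rep(1:3, times = c(30, 45, 25))
  feats <- centers[truth, ] + matrix(rnorm(100 * 40, 0, 0.4), 100)
  cm <- functional_clusters(feats, k_range = 1:8, seed = 3)
  expect_equal(cm$k, 3)
  expect_gte(adjusted_rand(truth, cm$assignments), 0.9)
  expect_gt(cm$silhouette, 0.5)
  # identical inputs across seeds of the same call
  cm2 <- functional_clusters(feats, k_range = 1:8, seed = 3)
  expect_identical(cm$assignments, cm2$assignments)
  # inertia nonincreasing in k
  expect_true(all(diff(cm$elbow_curve$inertia) <= 1e-8))
})

test_that("degenerate feature sets collapse to one cluster", {
  feats <- matrix(1, 30, 10) + 0
  feats <- feats + matrix(rnorm(300, 0, 1e-9), 30)
  cm <- functional_clusters(feats, k_range = 1:5, seed = 1)
  expect_equal(cm$k, 1)
  expect_lt(cm$elbow_curve$inertia[1], 1e-10)
})

test_that("clustering is invariant to neuron order up to relabeling", {
  set.seed(4)
  centers <- matrix(rnorm(4 * 20, sd = 4), 4)
  truth <- rep(1:4, each = 20)
  feats <- centers[truth, ] + matrix(rnorm(80 * 20, 0, 0.3), 80)
  cm1 <- functional_clusters(feats, k_range = 1:8, seed = 5)
  perm <- sample(80)
  cm2 <- functional_clusters(feats[perm, ], k_range = 1:8, seed = 5)
  expect_equal(cm1$k, cm2$k)
  expect_gte(adjusted_rand(cm1$assignments[perm], cm2$assignments), 0.999)
})

test_that("cluster profiles normalize rows to [0,1] and average members", {
  set.seed(5)
  feats <- rbind(matrix(rep(c(0, 2, 1), 4), 4, 3, byrow = TRUE),
                 matrix(rnorm(12), 4))
  cm <- list(k = 2, assignments = rep(1:2, each = 4))
  class(cm) <- "cluster_model"
  pf <- cluster_profiles(cm, feats)
  expect_equal(unname(apply(pf$normalized, 1, min)), rep(0, 8))
  expect_equal(unname(apply(pf$normalized, 1, max)), rep(1, 8))
  # identical members: cluster mean equals each member
  expect_equal(pf$cluster_means[1, ], feats[1, ])
  # constant neuron maps to 0.5
  featc <- rbind(feats, 5)
  cmc <- list(k = 2, assignments = c(rep(1:2, each = 4), 2))
  class(cmc) <- "cluster_model"
  expect_true(all(cluster_profiles(cmc, featc)$normalized[9, ] == 0.5))
})

test_that("planted motif clusters correlate with their templates", {
  cfg <- sim_config(n_neurons = 300, n_trials = 24, seed = 6)
  s <- preprocess_session(generate_session(cfg))
  ts_ <- cs_tensors(s)
  tsh <- build_trial_tensor(s, "shock_onset", c(-2, 2))
  trn <- build_trial_tensor(s, "avrun_onset", c(-2, 2))
  feats <- epoch_feature_matrix(list(cs_success = ts_$S, cs_failure = ts_$F,
                                     shock = tsh, avrun = trn))
  cm <- functional_clusters(feats, seed = 7)
  pf <- cluster_profiles(cm, feats)
  # each cluster's mean correlates strongly with its members' motif mean
  gt <- s$ground_truth$motif_id
  for (j in seq_len(cm$k)) {
    members <- cm$assignments == j
    dom <- as.integer(names(which.max(table(gt[members]))))
    template <- colMeans(feats[gt == dom, , drop = FALSE])
    if (sd(template) < 1e-3) next   # unresponsive motif has a flat template
    expect_gt(cor(pf$cluster_means[j, ], template), 0.9)
  }
})

test_that("spatial concentration profiles are well-formed and calibrated cases behave", {
  set.seed(8)
  coords <- runif(200, 0, 1)
  vals <- rnorm(200, 5, 1)
  st <- spatial_concentration_test(vals, coords, n_shuffle = 500, seed = 1)
  expect_equal(sum(st$relative_concentration), 1, tolerance = 1e-10)
  expect_equal(length(st$relative_concentration), 8)
  # constant values: zero statistic, p = 1
  stc <- spatial_concentration_test(rep(2, 200), coords, n_shuffle = 200,
                                    seed = 1)
  expect_equal(stc$statistic, 0)
  expect_equal(stc$p_value, 1)
  # values packed into one bin: decisively significant
  v <- as.numeric(coords < 0.125)
  stp <- spatial_concentration_test(v, coords, n_shuffle = 1000, seed = 2)
  expect_lt(stp$p_value, 0.05)
  # reproducible under the seed
  expect_identical(spatial_concentration_test(vals, coords,
                                              n_shuffle = 300, seed = 5),
                   spatial_concentration_test(vals, coords,
                                              n_shuffle = 300, seed = 5))
})

test_that("family-wise spatial testing applies Holm-Bonferroni across tests", {
  set.seed(9)
  coords <- data.frame(ap_mm = runif(150), ml_mm = runif(150),
                       dv_mm = runif(150))
  vl <- list(a = rnorm(150), b = rnorm(150))
  out <- spatial_test_family(vl, coords, n_shuffle = 300, seed = 1)
  expect_equal(nrow(out), 6)
  expect_true(all(out$corrected_p >= out$p_value - 1e-12))
  expect_equal(out$corrected_p,
               p.adjust(out$p_value, method = "holm"))
})
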