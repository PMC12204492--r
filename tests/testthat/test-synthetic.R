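test_that("trial outcomes follow the Bernoulli draw fixed by the seed", {
  cfg <- sim_config(n_trials = 30, p_success = 0.7, seed = 42)
  s <- generate_session(cfg)
  # independent oracle: outcomes are the first n_trials uniform draws
  set.seed(42)
  expect_equal(s$events$outcome,
               ifelse(runif(30) < 0.7, "success", "failure"))
  # long-run rate sanity over several seeds
  rate <- mean(vapply(1:8, function(sd_) {
    mean(generate_session(sim_config(n_trials = 30, seed = sd_))$events$outcome
         == "success")
  }, numeric(1)))
  expect_gt(rate, 0.55)
  expect_lt(rate, 0.85)
})

test_that("generated event tables satisfy the task invariants", {
  for (sd_ in 1:5) {
    ev <- generate_session(sim_config(n_trials = 20, seed = sd_))$events
    expect_true(all(ev$cs_offset_s > ev$cs_onset_s))
    succ <- ev$outcome == "success"
    expect_true(all(ev$cs_offset_s[succ] - ev$cs_onset_s[succ] <= 10 + 1e-9))
    expect_true(all(is.finite(ev$shock_onset_s[!succ])))
    lat <- ev$avrun_onset_s[succ] - ev$cs_onset_s[succ]
    expect_true(all(lat >= 4 & lat < 10))
    # ITIs respect the configured range (CS onset spacing minus the
    # fixed 15-s post-CS block)
    gaps <- diff(ev$cs_onset_s) - 15
    expect_true(all(gaps >= 25 - 1e-9 & gaps <= 40 + 1e-9))
  }
})

test_that("noiseless single-neuron trace equals the planted kernel train", {
  cfg <- one_motif_cfg(c(cs_success = 1), n_trials = 8, p_success = 1,
                       seed = 3)
  s <- suppressWarnings(generate_session(cfg))
  fr <- cfg$frame_rate_hz
  kern <- gcamp_kernel(fr)
  manual <- numeric(ncol(s$traces))
  for (t0 in s$events$cs_onset_s) {
    f <- floor(t0 * fr) + 1
    idx <- f:min(length(manual), f + length(kern) - 1)
    manual[idx] <- manual[idx] + kern[seq_along(idx)]
  }
  expect_equal(unname(s$traces[1, ]), manual, tolerance = 1e-10)
})

test_that("fixed seed fixes every output bitwise; sessions differ across seeds", {
  cfg <- sim_config(n_neurons = 8, n_trials = 6, seed = 9)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$behavior$xy, b$behavior$xy)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  co <- generate_cohort(cfg, 2)
  expect_false(identical(co[[1]]$traces, co[[2]]$traces))
  co2 <- generate_cohort(cfg, 2)
  expect_identical(co[[2]]$traces, co2[[2]]$traces)
})

test_that("cohort spatial coordinates concentrate at the motif locus", {
  m <- list(motifs = list(motif_spec("tight", c(cs_success = 1),
                                     spatial_center = c(0.5, 0.3, 2.9),
                                     spatial_sd = 1e-9)),
            proportions = 1)
  cfg <- sim_config(n_neurons = 30, n_trials = 5, motifs = m, seed = 4)
  s <- generate_session(cfg)
  expect_equal(s$neurons$ap_mm, rep(0.5, 30), tolerance = 1e-6)
  expect_equal(s$neurons$dv_mm, rep(2.9, 30), tolerance = 1e-6)
})

test_that("degenerate outcome probabilities warn about single-class sessions", {
  expect_warning(generate_session(sim_config(n_trials = 5, p_success = 1,
                                             seed = 1)),
                 "single-class")
})

test_that("photometry channels decompose as planted", {
  cfg <- sim_config(n_trials = 8, seed = 5)
  # artifact amplitude 0: 465 = signal + noise only, 405 pure noise
  ph0 <- generate_photometry(cfg, c(cs_success = 1), artifact_sd = 0,
                             noise_sd = 1e-8)
  expect_equal(ph0$sig465, ph0$ground_truth$signal, tolerance = 1e-5)
  # signal 0, artifact > 0: correction removes nearly everything
  ph <- generate_photometry(cfg, c(cs_success = 0), artifact_sd = 0.5,
                            noise_sd = 0.01)
  off <- 10 - min(ph$sig465, ph$sig405)
  z <- isosbestic_correct(ph$sig465 + off, ph$sig405 + off, rate_hz = 30)
  expect_lt(stats::sd(z) / stats::sd(100 * ph$sig465 / 10), 0.35)
  expect_lt(max(abs(scale(z))), 6)
})

test_that("input-count generator matches its Dirichlet-multinomial design", {
  prof <- default_region_profiles()
  # concentration -> infinity: proportions converge to the profile
  icm <- generate_input_counts(3, prof, concentration = 1e7,
                               total_cells = 200000, seed = 2)
  pr <- input_proportions(icm)
  for (st in names(prof)) {
    rows <- pr$props[pr$subtype == st, , drop = FALSE]
    expect_equal(colMeans(rows), prof[[st]], tolerance = 0.01)
  }
  expect_true(all(rowSums(icm$counts) == 200000))
  # inconsistent region lists are rejected
  bad <- prof
  names(bad$Chat) <- rev(names(bad$Chat))
  expect_error(generate_input_counts(2, bad, 10, 100), "region lists")
})
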