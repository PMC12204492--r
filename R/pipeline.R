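#' Pipeline configuration
#'
#' Accepts a YAML file path or a list; fills defaults for every stage
#' parameter. The single global `seed` deterministically derives a
#' per-stage seed (stage-name hash), so any stage is reproducible in
#' isolation.
#'
#' @param config list or path to a YAML file.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    stages = c("simulate", "preprocess", "modulate", "geometry",
               "decode", "cluster", "glm", "connectivity"),
    seed = 1L,
    out_dir = NULL,
    sim = list(n_neurons = 60, n_trials = 30, n_sessions = 1,
               frame_rate_hz = 5, p_success = 0.7, noise_sd = 1),
    modulation = list(variables = c("cs", "avrun", "pre_avrun", "shock"),
                      n_perm = 1000, alpha = 0.05),
    geometry = list(window_cs = c(-2, 3), window_avrun = c(-3, 3),
                    cd_window = c(0, 3), n_boot = 100,
                    variance_target = 0.8),
    decode = list(period_cs = c(0, 2), period_preavrun = c(-1.4, 0),
                  n_neurons = 50, n_boot = 100, n_shuffle = 100),
    cluster = list(k_range = 1:20, variance_target = 0.8, replicates = 5,
                   n_bins = 8, n_shuffle = 1000),
    glm = list(optimize_shifts = FALSE),
    connectivity = list(n_subjects = 5, concentration = 60,
                        total_cells = 2000, n_perm = 200, n_boot = 200))
  cfg <- utils::modifyList(defaults, config)
  known <- c("simulate", "preprocess", "modulate", "geometry", "decode",
             "cluster", "glm", "connectivity")
  bad <- setdiff(cfg$stages, c(known, "all"))
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if ("all" %in% cfg$stages) cfg$stages <- known
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 1009 + h) %% .Machine$integer.max)
}

stage_log <- function(stage, seed, ...) {
  message(sprintf("[%s] seed=%d %s", stage, seed,
                  paste(..., collapse = " ")))
}

write_result <- function(out_dir, name, df) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(df, file.path(out_dir, paste0(name, ".csv")))
}

#' Run the analysis pipeline on synthetic (or provided) sessions
#'
#' Executes the requested stages in dependency order
#' (simulate/preprocess before any analysis stage), writes result CSVs
#' to `config$out_dir` when set, and logs each stage with its derived
#' seed and parameters.
#'
#' @param config `pipeline_config`, list, or YAML path.
#' @param sessions optional list of `session_bundle`s to analyze instead
#'   of simulating.
#' @return named list of stage results.
#' @export
run_pipeline <- function(config = list(), sessions = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  stages <- cfg$stages
  res <- list(config = cfg)
  needs_pre <- c("modulate", "geometry", "decode", "cluster", "glm")
  if (any(stages %in% needs_pre) && !"preprocess" %in% stages) {
    stop("dependency error: ",
         paste(intersect(stages, needs_pre), collapse = ", "),
         " require(s) the preprocess stage")
  }
  if ("preprocess" %in% stages && is.null(sessions) &&
      !"simulate" %in% stages) {
    stop("dependency error: preprocess requires simulate or input sessions")
  }

  if ("simulate" %in% stages && is.null(sessions)) {
    sd_ <- stage_seed(cfg$seed, "simulate")
    stage_log("simulate", sd_, sprintf("n_sessions=%d n_neurons=%d",
                                       cfg$sim$n_sessions,
                                       cfg$sim$n_neurons))
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = sd_)))
    sessions <- generate_cohort(scfg)
    res$sessions <- sessions
    gt <- do.call(rbind, lapply(sessions, function(s) {
      data.frame(session_id = s$session_id,
                 neuron_id = s$neurons$neuron_id,
                 motif = s$ground_truth$motif_name)
    }))
    write_result(cfg$out_dir, "ground_truth", gt)
  }

  if ("preprocess" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "preprocess")
    stage_log("preprocess", sd_, sprintf("n_sessions=%d", length(sessions)))
    sessions <- lapply(sessions, preprocess_session)
    res$sessions <- sessions
    ztab <- do.call(rbind, lapply(sessions, function(s) {
      data.frame(session_id = s$session_id,
                 neuron_id = s$neurons$neuron_id,
                 z_mean = rowMeans(s$z), z_sd = apply(s$z, 1, stats::sd))
    }))
    write_result(cfg$out_dir, "preprocess_zscore", ztab)
  }

  # pooled tensors across sessions (pseudo-population pooling)
  pool_tensor <- function(align, win, outcome = NULL) {
    tl <- lapply(sessions, function(s) {
      t <- try(build_trial_tensor(s, align, win), silent = TRUE)
      if (inherits(t, "try-error")) return(NULL)
      if (!is.null(outcome)) {
        t <- try(tensor_by_outcome(t, outcome), silent = TRUE)
        if (inherits(t, "try-error")) return(NULL)
      }
      t
    })
    tl <- Filter(Negate(is.null), tl)
    if (!length(tl)) stop("no sessions yield trials for ", align)
    n_tr <- min(vapply(tl, function(t) dim(t$data)[2], 1L))
    out <- tl[[1]]
    out$data <- do.call(abind_n, lapply(tl, function(t) {
      t$data[, seq_len(n_tr), , drop = FALSE]
    }))
    out$outcome <- rep(out$outcome[seq_len(n_tr)], 1)
    out
  }

  if ("modulate" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "modulate")
    stage_log("modulate", sd_,
              sprintf("n_perm=%d alpha=%g", cfg$modulation$n_perm,
                      cfg$modulation$alpha))
    mods <- lapply(cfg$modulation$variables, function(v) {
      do.call(rbind, lapply(sessions, function(s) {
        circular_null_classify(s, v, n_perm = cfg$modulation$n_perm,
                               alpha = cfg$modulation$alpha, seed = sd_)
      }))
    })
    names(mods) <- cfg$modulation$variables
    res$modulation <- mods
    res$modulation_summary <- modulation_summary(mods)
    write_result(cfg$out_dir, "modulation", do.call(rbind, mods))
    write_result(cfg$out_dir, "modulation_summary", res$modulation_summary)
  }

  if (any(c("geometry", "decode", "cluster") %in% stages)) {
    tS <- pool_tensor("cs_onset", cfg$geometry$window_cs, "success")
    tF <- pool_tensor("cs_onset", cfg$geometry$window_cs, "failure")
  }

  if ("geometry" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "geometry")
    stage_log("geometry", sd_, sprintf("n_boot=%d", cfg$geometry$n_boot))
    emb <- trial_averaged_pca(tS, tF)
    div <- trajectory_divergence(tS, tF, n_boot = cfg$geometry$n_boot,
                                 variance_target =
                                   cfg$geometry$variance_target,
                                 baseline_window = c(-2, 0), seed = sd_)
    cd <- coding_direction(tS, tF, window_s = cfg$geometry$cd_window)
    res$geometry <- list(embedding = emb, divergence = div, cd = cd,
                         residual = residual_pcs(cd, tS, tF))
    write_result(cfg$out_dir, "divergence",
                 data.frame(t_s = div$t_s, mean_z = div$mean_z,
                            significant = div$significant))
    write_result(cfg$out_dir, "coding_direction",
                 data.frame(neuron = seq_along(cd$cd), cd = cd$cd))
  }

  if ("decode" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "decode")
    stage_log("decode", sd_, sprintf("n_neurons=%d n_boot=%d",
                                     cfg$decode$n_neurons,
                                     cfg$decode$n_boot))
    dw <- decode_window(tS, tF, period_s = cfg$decode$period_cs,
                        n_neurons = min(cfg$decode$n_neurons,
                                        dim(tS$data)[1]),
                        n_boot = cfg$decode$n_boot, seed = sd_)
    nul <- shuffle_null(tS, tF, period_s = cfg$decode$period_cs,
                        n_neurons = min(cfg$decode$n_neurons,
                                        dim(tS$data)[1]),
                        n_shuffle = cfg$decode$n_shuffle,
                        observed = dw$mean_accuracy, seed = sd_ + 1L)
    res$decode <- list(window = dw, null = nul)
    write_result(cfg$out_dir, "decode_window",
                 data.frame(bootstrap = seq_along(dw$accuracies),
                            accuracy = dw$accuracies))
  }

  if ("cluster" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "cluster")
    stage_log("cluster", sd_, sprintf("k_range=1..%d",
                                      max(cfg$cluster$k_range)))
    tShock <- pool_tensor("shock_onset", c(-2, 2))
    tRun <- pool_tensor("avrun_onset", c(-2, 2))
    feats <- epoch_feature_matrix(list(cs_success = tS, cs_failure = tF,
                                       shock = tShock, avrun = tRun))
    cm <- functional_clusters(feats, k_range = cfg$cluster$k_range,
                              variance_target =
                                cfg$cluster$variance_target,
                              replicates = cfg$cluster$replicates,
                              seed = sd_)
    coords <- do.call(rbind, lapply(sessions, function(s) {
      s$neurons[, c("ap_mm", "ml_mm", "dv_mm")]
    }))
    vl <- lapply(seq_len(cm$k), function(j) as.numeric(cm$assignments == j))
    names(vl) <- paste0("cluster", seq_len(cm$k))
    sp <- spatial_test_family(vl, coords, n_bins = cfg$cluster$n_bins,
                              n_shuffle = cfg$cluster$n_shuffle,
                              seed = sd_)
    res$cluster <- list(model = cm, spatial = sp,
                        profiles = cluster_profiles(cm, feats))
    write_result(cfg$out_dir, "cluster_assignments",
                 data.frame(neuron = seq_along(cm$assignments),
                            cluster = cm$assignments))
    write_result(cfg$out_dir, "cluster_elbow", cm$elbow_curve)
    write_result(cfg$out_dir, "spatial_tests", sp)
  }

  if ("glm" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "glm")
    stage_log("glm", sd_, sprintf("optimize_shifts=%s",
                                  cfg$glm$optimize_shifts))
    fits <- do.call(rbind, lapply(sessions, function(s) {
      f <- fit_session_glms(s, optimize_shifts = cfg$glm$optimize_shifts)
      cbind(session_id = s$session_id, f)
    }))
    res$glm <- list(fits = fits, indices = derived_indices(fits))
    write_result(cfg$out_dir, "glm_fits", fits)
    write_result(cfg$out_dir, "glm_indices", res$glm$indices$summary)
  }

  if ("connectivity" %in% stages) {
    sd_ <- stage_seed(cfg$seed, "connectivity")
    stage_log("connectivity", sd_,
              sprintf("n_subjects=%d", cfg$connectivity$n_subjects))
    icm <- generate_input_counts(cfg$connectivity$n_subjects,
                                 default_region_profiles(),
                                 concentration =
                                   cfg$connectivity$concentration,
                                 total_cells = cfg$connectivity$total_cells,
                                 seed = sd_)
    pr <- input_proportions(icm)
    res$connectivity <- list(
      anova = region_anova(pr$props, pr$subtype),
      pca = connectivity_pca_similarity(pr$props, pr$subtype,
                                        n_perm = cfg$connectivity$n_perm,
                                        seed = sd_),
      decoder = subtype_decoder(pr$props, pr$subtype,
                                n_boot = cfg$connectivity$n_boot,
                                n_perm = cfg$connectivity$n_perm,
                                seed = sd_))
    write_result(cfg$out_dir, "connectivity_anova",
                 res$connectivity$anova$table)
  }

  res
}

# bind arrays along the first (neuron) dimension
abind_n <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1) return(arrs[[1]])
  d <- dim(arrs[[1]])
  n_tot <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(n_tot, d[2], d[3]))
  off <- 0L
  for (a in arrs) {
    out[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  out
}
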