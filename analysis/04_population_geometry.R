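#!/usr/bin/env Rscript
# Population trajectory analysis: trial-averaged PCA over concatenated
# success/failure responses, bootstrapped Mahalanobis divergence between
# outcome trajectories, the outcome coding direction, and residual PCs
# orthogonal to it.

library(avoidpop)

data_dir <- "results/data"
out <- "results/tables"
fig <- "results/figures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(fig, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

sessions <- lapply(list.dirs(data_dir, recursive = FALSE),
                   read_session_bundle)
sessions <- lapply(sessions, preprocess_session)

# pool neurons across sessions at matched trial counts (pseudo-population)
tensors <- lapply(sessions, function(s) {
  tc <- build_trial_tensor(s, "cs_onset", c(-2, 3))
  list(S = tensor_by_outcome(tc, "success"),
       F = tensor_by_outcome(tc, "failure"))
})
nS <- min(vapply(tensors, function(t) dim(t$S$data)[2], 1L))
nF <- min(vapply(tensors, function(t) dim(t$F$data)[2], 1L))
pool <- function(which_, n_keep) {
  t0 <- tensors[[1]][[which_]]
  t0$data <- do.call(avoidpop:::abind_n, lapply(tensors, function(t) {
    t[[which_]]$data[, seq_len(n_keep), , drop = FALSE]
  }))
  t0$outcome <- t0$outcome[seq_len(n_keep)]
  t0
}
tS <- pool("S", nS)
tF <- pool("F", nF)
message(sprintf("pooled tensors: %d neurons, %d/%d success/failure trials",
                dim(tS$data)[1], nS, nF))

emb <- trial_averaged_pca(tS, tF)
message(sprintf("variance explained by PCs 1-3: %s",
                paste(round(100 * emb$explained_variance_ratio[1:3], 1),
                      collapse = " / ")))
write.csv(data.frame(pc = seq_along(emb$explained_variance_ratio),
                     evr = emb$explained_variance_ratio),
          file.path(out, "pca_variance.csv"), row.names = FALSE)

div <- trajectory_divergence(tS, tF, n_boot = 100,
                             baseline_window = c(-2, 0), seed = seed)
write.csv(data.frame(t_s = div$t_s, mean_z = div$mean_z,
                     significant = div$significant),
          file.path(out, "trajectory_divergence.csv"), row.names = FALSE)
message(sprintf("divergence significant from t = %.1f s after CS onset",
                min(div$t_s[div$significant])))

cd <- coding_direction(tS, tF, window_s = c(0, 3))
rp <- residual_pcs(cd, tS, tF)
write.csv(data.frame(neuron = seq_along(cd$cd), cd_coef = cd$cd,
                     residual_pc1 = rp$components[, 1]),
          file.path(out, "coding_direction.csv"), row.names = FALSE)
w <- which(tS$t_s >= 0 & tS$t_s < 3)
message(sprintf("CD projections (0-3 s): success %.2f, failure %.2f",
                mean(cd$projections_success[, w]),
                mean(cd$projections_failure[, w])))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dd <- data.frame(t_s = div$t_s, z = div$mean_z, sig = div$significant)
  p <- ggplot(dd, aes(t_s, z)) +
    geom_line() +
    geom_point(data = subset(dd, sig), color = "red", size = 1) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "time from CS onset (s)",
         y = "Mahalanobis distance (z to baseline)",
         title = "Success vs failure trajectory divergence") +
    theme_classic()
  ggsave(file.path(fig, "trajectory_divergence.png"), p,
         width = 5, height = 3.5, dpi = 150)
}
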