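#' Denoise a trial tensor through the trial-averaged PC subspace
#'
#' Reconstructs every single-trial population vector from the top PCs
#' reaching the variance target (projection onto the subspace plus the
#' row means), the representation used for pseudo-population decoding.
#'
#' @param embedding `population_embedding`.
#' @param tensor `trial_tensor`.
#' @param variance_target cumulative explained variance (0.8); 1 keeps
#'   all components (identity reconstruction).
#' @return tensor with reconstructed `data`.
#' @export
denoise_tensor <- function(embedding, tensor, variance_target = 0.8) {
  k <- n_pcs_for_variance(embedding$explained_variance_ratio,
                          variance_target)
  W <- embedding$components[, seq_len(k), drop = FALSE]
  n_tr <- dim(tensor$data)[2]
  for (tr in seq_len(n_tr)) {
    Xc <- tensor$data[, tr, ] - embedding$row_means
    tensor$data[, tr, ] <- W %*% (t(W) %*% Xc) + embedding$row_means
  }
  tensor
}

#' Assemble pseudo-population trial vectors
#'
#' Samples `n_neurons` without replacement, pairs trials at random within
#' each class (each neuron contributes an independently permuted trial),
#' and concatenates the period's timepoints per neuron into one feature
#' vector per pseudo-trial. The pseudo-trial count per class is the
#' minimum trial count across classes.
#'
#' @param tensorS,tensorF success / failure `trial_tensor`s (optionally
#'   denoised via [denoise_tensor()]).
#' @param period_s feature window in tensor time, e.g. `c(0, 2)` for the
#'   CS period or `c(-1.4, 0)` preceding the run.
#' @param n_neurons neurons to sample.
#' @param seed RNG seed.
#' @return list with `features` (pseudo-trials x (n_neurons * t)),
#'   `labels` (factor success/failure), `neuron_idx`, `period_cols`.
#' @export
build_pseudopopulation <- function(tensorS, tensorF, period_s, n_neurons,
                                   seed = 1L) {
  n_pool <- dim(tensorS$data)[1]
  if (n_neurons > n_pool) stop("n_neurons exceeds available neurons")
  cols <- tensor_window_cols(tensorS, period_s)
  if (!length(cols)) stop("period outside tensor window")
  nS <- dim(tensorS$data)[2]; nF <- dim(tensorF$data)[2]
  if (nS == 0 || nF == 0) stop("a class has no trials")
  n_pt <- min(nS, nF)
  set.seed(seed)
  sel <- sample.int(n_pool, n_neurons)
  feat_class <- function(tensor, n_avail) {
    out <- matrix(NA_real_, n_pt, n_neurons * length(cols))
    for (j in seq_along(sel)) {
      perm <- sample.int(n_avail, n_pt)
      block <- (j - 1) * length(cols) + seq_along(cols)
      for (pt in seq_len(n_pt)) {
        out[pt, block] <- tensor$data[sel[j], perm[pt], cols]
      }
    }
    out
  }
  fS <- feat_class(tensorS, nS)
  fF <- feat_class(tensorF, nF)
  list(features = rbind(fS, fF),
       labels = factor(rep(c("success", "failure"), each = n_pt)),
       neuron_idx = sel, period_cols = cols)
}

#' Stratified leave-one-out accuracy of a linear SVM
#'
#' Folds hold out one trial from each class; features are standardized
#' with statistics fit on the training folds only.
#'
#' @param X features (trials x features).
#' @param y factor with two or more classes, equal trial counts assumed
#'   per class for the stratified folds.
#' @param cost SVM regularization constant (1).
#' @param standardize z-score features on training statistics.
#' @return fraction of held-out trials classified correctly.
#' @export
svm_loo_accuracy <- function(X, y, cost = 1, standardize = TRUE) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least two classes")
  per_class <- split(seq_along(y), y)
  n_folds <- min(lengths(per_class))
  if (n_folds < 2) stop("need at least 2 trials per class")
  correct <- 0L; total <- 0L
  for (f in seq_len(n_folds)) {
    hold <- vapply(per_class, `[`, integer(1), f)
    train <- setdiff(seq_along(y), hold)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[hold, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    fit <- e1071::svm(Xtr, y[train], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte)
    correct <- correct + sum(pred == y[hold])
    total <- total + length(hold)
  }
  correct / total
}

#' Window decoder: outcome from pseudo-population period activity
#'
#' Per bootstrap the pseudo-population is reassembled (new neuron sample
#' and trial pairing) and scored by stratified leave-one-out
#' cross-validation of a linear SVM.
#'
#' @param tensorS,tensorF condition tensors (denoised upstream if wanted).
#' @param period_s feature window (s).
#' @param n_neurons neurons per pseudo-population.
#' @param n_boot bootstrap iterations (100).
#' @param cost,standardize classifier settings.
#' @param seed RNG seed.
#' @return list of class `decode_result`: `mode`, `n_neurons`,
#'   `accuracies` (per bootstrap), `mean_accuracy`.
#' @export
decode_window <- function(tensorS, tensorF, period_s = c(0, 2),
                          n_neurons = 200, n_boot = 100, cost = 1,
                          standardize = TRUE, seed = 1L) {
  acc <- vapply(seq_len(n_boot), function(b) {
    pp <- build_pseudopopulation(tensorS, tensorF, period_s, n_neurons,
                                 seed = seed + b - 1L)
    svm_loo_accuracy(pp$features, pp$labels, cost, standardize)
  }, numeric(1))
  structure(list(mode = "window", period_s = period_s,
                 n_neurons = n_neurons, accuracies = acc,
                 mean_accuracy = mean(acc)),
            class = "decode_result")
}

#' Time-resolved decoder: one classifier per time bin
#'
#' Instantaneous pseudo-population vectors (one value per neuron per bin)
#' are decoded independently at every timepoint of the tensor window.
#'
#' @inheritParams decode_window
#' @return list of class `decode_result` with `accuracies`
#'   (bootstraps x time bins), `mean_accuracy` per bin, `t_s`.
#' @export
decode_timecourse <- function(tensorS, tensorF, n_neurons = 200,
                              n_boot = 100, cost = 1, standardize = TRUE,
                              seed = 1L) {
  n_t <- dim(tensorS$data)[3]
  acc <- matrix(NA_real_, n_boot, n_t)
  full_win <- tensorS$window_s
  for (b in seq_len(n_boot)) {
    pp <- build_pseudopopulation(tensorS, tensorF, full_win, n_neurons,
                                 seed = seed + b - 1L)
    n_feat_per_neuron <- length(pp$period_cols)
    for (tt in seq_len(n_t)) {
      keep <- seq(tt, ncol(pp$features), by = n_feat_per_neuron)
      acc[b, tt] <- svm_loo_accuracy(pp$features[, keep, drop = FALSE],
                                     pp$labels, cost, standardize)
    }
  }
  structure(list(mode = "timecourse", n_neurons = n_neurons,
                 accuracies = acc, mean_accuracy = colMeans(acc),
                 t_s = tensorS$t_s),
            class = "decode_result")
}

#' Label-shuffle null distribution for a decoder
#'
#' Class labels are permuted and the full train/test procedure rerun per
#' shuffle; the p-value uses the add-one convention
#' `(1 + #(null >= observed)) / (1 + n_shuffle)`.
#'
#' @param tensorS,tensorF condition tensors.
#' @param period_s feature window.
#' @param n_neurons neurons per pseudo-population.
#' @param n_shuffle shuffles (1000).
#' @param observed observed accuracy to compare against (e.g.
#'   `decode_window(...)$mean_accuracy`).
#' @param cost,standardize classifier settings.
#' @param seed RNG seed.
#' @return list with `null_accuracies`, `p_value`, `observed`.
#' @export
shuffle_null <- function(tensorS, tensorF, period_s = c(0, 2),
                         n_neurons = 200, n_shuffle = 1000,
                         observed = NULL, cost = 1, standardize = TRUE,
                         seed = 1L) {
  null_acc <- vapply(seq_len(n_shuffle), function(s) {
    pp <- build_pseudopopulation(tensorS, tensorF, period_s, n_neurons,
                                 seed = seed + s - 1L)
    yshuf <- sample(pp$labels)
    svm_loo_accuracy(pp$features, yshuf, cost, standardize)
  }, numeric(1))
  p <- if (is.null(observed)) NA_real_ else {
    (1 + sum(null_acc >= observed)) / (1 + n_shuffle)
  }
  list(null_accuracies = null_acc, p_value = p, observed = observed)
}
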