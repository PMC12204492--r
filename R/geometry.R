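#' Trial-averaged population PCA over concatenated trial types
#'
#' Averages each tensor over trials, concatenates success and failure
#' means along time into an n x 2t matrix, mean-centers each neuron's row,
#' and extracts principal components over the time samples.
#'
#' @param tensorS,tensorF `trial_tensor`s (success / failure) sharing
#'   neurons and window.
#' @param n_pcs optional cap on returned components.
#' @return list of class `population_embedding`: `components`
#'   (neurons x PCs, unit columns), `explained_variance_ratio`,
#'   `concat_means` (n x 2t), `row_means`, `scores` (2t x PCs),
#'   `align_event`, `window_s`, `n_time`.
#' @export
trial_averaged_pca <- function(tensorS, tensorF, n_pcs = NULL) {
  if (dim(tensorS$data)[1] != dim(tensorF$data)[1]) {
    stop("success/failure tensors must share neurons")
  }
  mS <- apply(tensorS$data, c(1, 3), mean)
  mF <- apply(tensorF$data, c(1, 3), mean)
  X <- cbind(mS, mF)
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  n <- nrow(Xc)
  if (!is.null(n_pcs) && n < n_pcs) {
    stop("requested more PCs than neurons")
  }
  pc <- stats::prcomp(t(Xc), center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_pcs)) length(evr) else min(n_pcs, length(evr))
  structure(list(components = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(k)],
                 concat_means = X, row_means = rm_,
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 align_event = tensorS$align_event,
                 window_s = tensorS$window_s, n_time = ncol(mS)),
            class = "population_embedding")
}

n_pcs_for_variance <- function(evr, variance_target) {
  which(cumsum(evr) >= variance_target - 1e-12)[1]
}

#' Project single-trial activity onto the trial-averaged PC subspace
#'
#' @param embedding `population_embedding`.
#' @param tensor `trial_tensor` with the same neurons.
#' @param n_pcs number of PCs; default chooses the smallest number whose
#'   cumulative explained variance reaches `variance_target`.
#' @param variance_target cumulative variance threshold (0.8).
#' @return array trials x PCs x time.
#' @export
project_single_trials <- function(embedding, tensor, n_pcs = NULL,
                                  variance_target = 0.8) {
  if (nrow(embedding$components) != dim(tensor$data)[1]) {
    stop("neuron count mismatch between embedding and tensor")
  }
  if (is.null(n_pcs)) {
    n_pcs <- n_pcs_for_variance(embedding$explained_variance_ratio,
                                variance_target)
  }
  W <- embedding$components[, seq_len(n_pcs), drop = FALSE]
  n_tr <- dim(tensor$data)[2]
  n_t <- dim(tensor$data)[3]
  out <- array(NA_real_, c(n_tr, n_pcs, n_t))
  for (tr in seq_len(n_tr)) {
    Xt <- tensor$data[, tr, ] - embedding$row_means
    out[tr, , ] <- t(W) %*% Xt
  }
  out
}

ledoit_wolf_cov <- function(X) {
  # shrinkage toward the scaled identity (Ledoit-Wolf 2004)
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2)
  b2 <- 0
  for (k in seq_len(n)) {
    b2 <- b2 + sum((tcrossprod(Xc[k, ]) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  list(sigma = (1 - lambda) * S + lambda * diag(m, p), lambda = lambda)
}

#' Mahalanobis distance with optional shrinkage covariance
#'
#' @param a,b points (numeric vectors).
#' @param sigma covariance matrix; must be invertible.
#' @return `sqrt((a-b)' sigma^{-1} (a-b))`.
#' @export
mahalanobis_dist <- function(a, b, sigma) {
  d <- a - b
  drop(sqrt(sum(d * solve(sigma, d))))
}

pooled_shrunk_cov <- function(A, B) {
  p <- ncol(A)
  nA <- nrow(A); nB <- nrow(B)
  if (min(nA, nB) <= p) {
    ca <- ledoit_wolf_cov(A); cb <- ledoit_wolf_cov(B)
    sigma <- (nA * ca$sigma + nB * cb$sigma) / (nA + nB)
    attr(sigma, "shrunk") <- TRUE
    return(sigma)
  }
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  sigma <- (crossprod(Ac) + crossprod(Bc)) / (nA + nB - 2)
  if (rcond_ok(sigma)) {
    attr(sigma, "shrunk") <- FALSE
    sigma
  } else {
    ca <- ledoit_wolf_cov(A); cb <- ledoit_wolf_cov(B)
    out <- (nA * ca$sigma + nB * cb$sigma) / (nA + nB)
    attr(out, "shrunk") <- TRUE
    out
  }
}

rcond_ok <- function(S) {
  is.finite(rcond(S)) && rcond(S) > 1e-10
}

#' Bootstrapped Mahalanobis divergence between condition trajectories
#'
#' Per bootstrap a random neuron subset is drawn, the trial-averaged PCA
#' is refit, single trials are projected onto the PCs reaching the
#' variance target, and at each timepoint the Mahalanobis distance
#' between the success and failure trial clouds (pooled within-condition
#' covariance, Ledoit-Wolf shrinkage when trials are scarce) is computed,
#' along with each condition's distance from its own baseline-period
#' cloud. Distance series are z-scored to the baseline period within each
#' bootstrap. A timepoint is significant when fewer than `sig_frac` of
#' bootstraps give a between-condition z below `z_thresh`.
#'
#' @param tensorS,tensorF success / failure `trial_tensor`s.
#' @param n_boot bootstrap iterations (100).
#' @param variance_target cumulative variance for PC selection (0.8).
#' @param subsample_frac fraction of neurons drawn per bootstrap (0.8).
#' @param baseline_window seconds, e.g. `c(-2, 0)` for CS alignment,
#'   `c(-3, -2)` for run alignment.
#' @param z_thresh,sig_frac significance rule (1.65, 0.05).
#' @param seed RNG seed.
#' @return list with `t_s`, `z_between` (bootstraps x time),
#'   `mean_z`, `significant` (logical per timepoint), `z_within_success`,
#'   `z_within_failure`, `n_pcs_used`.
#' @export
trajectory_divergence <- function(tensorS, tensorF, n_boot = 100,
                                  variance_target = 0.8,
                                  subsample_frac = 0.8,
                                  baseline_window = c(-2, 0),
                                  z_thresh = 1.65, sig_frac = 0.05,
                                  seed = 1L) {
  if (dim(tensorS$data)[2] < 2 || dim(tensorF$data)[2] < 2) {
    stop("need at least 2 trials per condition")
  }
  n_neur <- dim(tensorS$data)[1]
  n_t <- dim(tensorS$data)[3]
  b_cols <- tensor_window_cols(tensorS, baseline_window)
  if (!length(b_cols)) stop("baseline window outside tensor")
  # equalize trial counts across conditions
  n_tr <- min(dim(tensorS$data)[2], dim(tensorF$data)[2])
  set.seed(seed)
  z_btw <- matrix(NA_real_, n_boot, n_t)
  z_wS <- matrix(NA_real_, n_boot, n_t)
  z_wF <- matrix(NA_real_, n_boot, n_t)
  k_used <- integer(n_boot)
  any_shrunk <- FALSE
  for (bt in seq_len(n_boot)) {
    sel <- sample.int(n_neur, max(2L, round(subsample_frac * n_neur)))
    tS <- tensorS; tS$data <- tS$data[sel, sample.int(dim(tS$data)[2], n_tr), , drop = FALSE]
    tF <- tensorF; tF$data <- tF$data[sel, sample.int(dim(tF$data)[2], n_tr), , drop = FALSE]
    emb <- trial_averaged_pca(tS, tF)
    k <- n_pcs_for_variance(emb$explained_variance_ratio, variance_target)
    k_used[bt] <- k
    pS <- project_single_trials(emb, tS, n_pcs = k)
    pF <- project_single_trials(emb, tF, n_pcs = k)
    baseS <- matrix(aperm(pS[, , b_cols, drop = FALSE], c(1, 3, 2)),
                    ncol = k)
    baseF <- matrix(aperm(pF[, , b_cols, drop = FALSE], c(1, 3, 2)),
                    ncol = k)
    d_btw <- numeric(n_t); d_wS <- numeric(n_t); d_wF <- numeric(n_t)
    for (tt in seq_len(n_t)) {
      A <- matrix(pS[, , tt], ncol = k)
      B <- matrix(pF[, , tt], ncol = k)
      sg <- pooled_shrunk_cov(A, B)
      if (isTRUE(attr(sg, "shrunk"))) any_shrunk <- TRUE
      d_btw[tt] <- mahalanobis_dist(colMeans(A), colMeans(B), sg)
      sgS <- pooled_shrunk_cov(A, baseS)
      d_wS[tt] <- mahalanobis_dist(colMeans(A), colMeans(baseS), sgS)
      sgF <- pooled_shrunk_cov(B, baseF)
      d_wF[tt] <- mahalanobis_dist(colMeans(B), colMeans(baseF), sgF)
    }
    zb <- function(d) {
      mu <- mean(d[b_cols]); s <- stats::sd(d[b_cols])
      if (s == 0) s <- 1
      (d - mu) / s
    }
    z_btw[bt, ] <- zb(d_btw)
    z_wS[bt, ] <- zb(d_wS)
    z_wF[bt, ] <- zb(d_wF)
  }
  if (any_shrunk) {
    message("trajectory_divergence: shrinkage covariance used (trials <= PCs)")
  }
  sig <- colMeans(z_btw < z_thresh) < sig_frac
  list(t_s = tensorS$t_s, z_between = z_btw, mean_z = colMeans(z_btw),
       significant = sig, z_within_success = colMeans(z_wS),
       z_within_failure = colMeans(z_wF), n_pcs_used = k_used)
}

#' Outcome coding direction and projections
#'
#' The difference between window-averaged success and failure population
#' vectors, normalized to unit length. Trials are projected after
#' subtracting the grand (cross-condition) mean vector, so the in-window
#' mean success projection is positive and the failure projection
#' negative by construction.
#'
#' @param tensorS,tensorF success / failure `trial_tensor`s.
#' @param window_s averaging window (default 0-3 s after the event).
#' @return list of class `coding_direction`: `cd` (unit vector or zeros),
#'   `zero_flag`, `window_s`, `projections_success`,
#'   `projections_failure` (trials x time), `grand_mean`, `t_s`.
#' @export
coding_direction <- function(tensorS, tensorF, window_s = c(0, 3)) {
  if (dim(tensorS$data)[1] != dim(tensorF$data)[1]) {
    stop("success/failure tensors must share neurons")
  }
  cols <- tensor_window_cols(tensorS, window_s)
  if (!length(cols)) stop("window outside tensor")
  mS <- apply(tensorS$data[, , cols, drop = FALSE], 1, mean)
  mF <- apply(tensorF$data[, , cols, drop = FALSE], 1, mean)
  d <- mS - mF
  nrm <- sqrt(sum(d^2))
  zero_flag <- nrm == 0
  cd <- if (zero_flag) d else d / nrm
  gm <- (mS + mF) / 2
  proj <- function(tensor) {
    n_tr <- dim(tensor$data)[2]; n_t <- dim(tensor$data)[3]
    out <- matrix(NA_real_, n_tr, n_t)
    for (tr in seq_len(n_tr)) {
      out[tr, ] <- drop(cd %*% (tensor$data[, tr, ] - gm))
    }
    out
  }
  structure(list(cd = cd, zero_flag = zero_flag, window_s = window_s,
                 projections_success = proj(tensorS),
                 projections_failure = proj(tensorF),
                 grand_mean = gm, t_s = tensorS$t_s),
            class = "coding_direction")
}

#' Principal components of activity orthogonal to the coding direction
#'
#' Removes the coding-direction component from the mean-centered
#' trial-averaged concatenated activity and extracts PCs of the residual;
#' all returned components are orthogonal to the CD.
#'
#' @param cd `coding_direction` (or unit vector).
#' @param tensorS,tensorF the condition tensors.
#' @param variance_target cumulative residual variance to keep (0.85).
#' @return list with `components` (neurons x k), `explained_variance_ratio`
#'   (of residual variance), `projections_success`, `projections_failure`
#'   (trials x k x time).
#' @export
residual_pcs <- function(cd, tensorS, tensorF, variance_target = 0.85) {
  v <- if (inherits(cd, "coding_direction")) cd$cd else cd
  mS <- apply(tensorS$data, c(1, 3), mean)
  mF <- apply(tensorF$data, c(1, 3), mean)
  X <- cbind(mS, mF)
  Xc <- X - rowMeans(X)
  if (sum(v^2) > 0) {
    Xres <- Xc - v %*% (t(v) %*% Xc)
  } else {
    Xres <- Xc
  }
  pc <- stats::prcomp(t(Xres), center = FALSE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  evr <- if (tot > 0) pc$sdev^2 / tot else pc$sdev^2
  k <- max(1L, n_pcs_for_variance(evr, variance_target))
  W <- pc$rotation[, seq_len(k), drop = FALSE]
  rm_ <- rowMeans(X)
  proj <- function(tensor) {
    n_tr <- dim(tensor$data)[2]; n_t <- dim(tensor$data)[3]
    out <- array(NA_real_, c(n_tr, k, n_t))
    for (tr in seq_len(n_tr)) {
      out[tr, , ] <- t(W) %*% (tensor$data[, tr, ] - rm_)
    }
    out
  }
  list(components = W, explained_variance_ratio = evr[seq_len(k)],
       residual_total_variance = tot,
       projections_success = proj(tensorS),
       projections_failure = proj(tensorF))
}
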