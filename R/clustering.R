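#' Concatenated epoch feature matrix for functional clustering
#'
#' Per neuron, the trial-averaged responses in the four behavioral epochs
#' (CS-success, CS-failure, shock, avoidance run) are concatenated into
#' one row.
#'
#' @param tensors named list with elements `cs_success`, `cs_failure`,
#'   `shock`, `avrun` (each a `trial_tensor` over the same neurons).
#' @return numeric matrix, neurons x total timepoints, with an
#'   `epoch_cols` attribute mapping columns to epochs.
#' @export
epoch_feature_matrix <- function(tensors) {
  need <- c("cs_success", "cs_failure", "shock", "avrun")
  miss <- setdiff(need, names(tensors))
  if (length(miss)) stop("missing epochs: ", paste(miss, collapse = ", "))
  n <- dim(tensors[[need[1]]]$data)[1]
  blocks <- lapply(need, function(e) {
    te <- tensors[[e]]
    if (dim(te$data)[1] != n) stop("epoch ", e, ": neuron count mismatch")
    apply(te$data, c(1, 3), mean)
  })
  out <- do.call(cbind, blocks)
  ep <- rep(need, vapply(blocks, ncol, 1L))
  attr(out, "epoch_cols") <- ep
  out
}

#' PCA + k-means functional clustering with elbow selection
#'
#' The feature matrix is reduced to the PCs explaining at least
#' `variance_target` of the variance; k-means is run for each k in
#' `k_range` with `replicates` restarts (best inertia kept); k is chosen
#' at the elbow, the maximum discrete second difference of the inertia
#' curve; the silhouette score validates the chosen partition.
#'
#' @param features neurons x time matrix (from [epoch_feature_matrix()]).
#' @param k_range candidate cluster counts (1:20).
#' @param variance_target cumulative PC variance (0.8).
#' @param replicates k-means restarts per k (5).
#' @param seed RNG seed.
#' @return list of class `cluster_model`: `k`, `assignments`,
#'   `centers_pc`, `pc_space` (neurons x PCs), `elbow_curve`
#'   (data.frame k / inertia), `silhouette`, `rotation`.
#' @export
functional_clusters <- function(features, k_range = 1:20,
                                variance_target = 0.8, replicates = 5,
                                seed = 1L) {
  n <- nrow(features)
  if (n < max(k_range)) stop("need at least max(k_range) neurons")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  kpc <- max(1L, n_pcs_for_variance(evr, variance_target))
  X <- pc$x[, seq_len(kpc), drop = FALSE]
  set.seed(seed)
  k_range <- sort(k_range)
  fits <- vector("list", length(k_range))
  # Ward-linkage centroids as a deterministic high-quality init candidate
  hc <- if (n <= 4000) stats::hclust(stats::dist(X), method = "ward.D2")
  prev <- NULL
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k == 1) {
      ctr <- matrix(colMeans(X), 1)
      fits[[ki]] <- list(cluster = rep(1L, n), centers = ctr,
                         tot.withinss = sum(sweep(X, 2, ctr)^2))
      prev <- fits[[ki]]
      next
    }
    fit <- stats::kmeans(X, centers = k, nstart = replicates,
                         iter.max = 100)
    tries <- 0
    while (length(unique(fit$cluster)) < k && tries < 5) {
      message("k-means k=", k, ": empty cluster, re-running")
      fit <- stats::kmeans(X, centers = k, nstart = replicates,
                           iter.max = 100)
      tries <- tries + 1
    }
    # additional deterministic inits: Ward centroids, and the previous
    # solution plus its worst-fit point (keeps the curve nonincreasing)
    cands <- list()
    if (!is.null(hc)) {
      cut <- stats::cutree(hc, k)
      cands$ward <- t(vapply(seq_len(k), function(j) {
        colMeans(X[cut == j, , drop = FALSE])
      }, numeric(ncol(X))))
    }
    if (!is.null(prev) && nrow(prev$centers) == k - 1) {
      d2 <- rowSums((X - prev$centers[prev$cluster, , drop = FALSE])^2)
      cands$warm <- rbind(prev$centers, X[which.max(d2), ])
    }
    for (init in cands) {
      if (anyDuplicated(init)) next
      alt <- tryCatch(stats::kmeans(X, centers = init, iter.max = 100),
                      error = function(e) NULL)
      if (!is.null(alt) && alt$tot.withinss < fit$tot.withinss) fit <- alt
    }
    fits[[ki]] <- fit
    prev <- fit
  }
  inertia <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  k_best <- if (inertia[1] <= 1e-10 * n) k_range[1] else
    elbow_k(k_range, inertia)
  best <- fits[[match(k_best, k_range)]]
  sil <- silhouette_score(X, best$cluster)
  structure(list(k = k_best, assignments = best$cluster,
                 centers_pc = best$centers, pc_space = X,
                 elbow_curve = data.frame(k = k_range, inertia = inertia),
                 silhouette = sil, rotation = pc$rotation[, seq_len(kpc),
                                                          drop = FALSE],
                 feature_center = pc$center),
            class = "cluster_model")
}

# elbow: k with the maximum discrete second difference of log-inertia.
# The log scale makes the curvature scale-invariant; raw differences are
# dominated by the first splits whenever cluster sizes are imbalanced.
elbow_k <- function(k_range, inertia) {
  if (length(k_range) < 3) return(k_range[which.min(inertia)])
  curve <- if (all(inertia > 0)) log(inertia) else inertia
  d2 <- diff(curve, differences = 2)     # at k_range[2:(n-1)]
  k_range[which.max(d2) + 1L]
}

# mean silhouette width over all points (Euclidean)
silhouette_score <- function(X, cluster) {
  k <- length(unique(cluster))
  if (k < 2) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(cluster), cluster[i]), function(cl) {
      mean(D[i, cluster == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster profiles and display ordering
#'
#' Per-cluster mean traces per epoch, per-neuron min-max normalization to
#' [0, 1] (constant rows map to 0.5), and within-cluster ordering by
#' correlation with the cluster mean.
#'
#' @param model `cluster_model`.
#' @param features the matrix the model was fit on.
#' @return list with `cluster_means` (k x time), `normalized`
#'   (neurons x time in [0,1]), `order` (row order for heatmaps),
#'   `epoch_cols`.
#' @export
cluster_profiles <- function(model, features) {
  k <- model$k
  cl <- model$assignments
  cm <- t(vapply(seq_len(k), function(j) {
    colMeans(features[cl == j, , drop = FALSE])
  }, numeric(ncol(features))))
  norm01 <- t(apply(features, 1, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0.5, length(x)) else (x - min(x)) / rng
  }))
  ord <- unlist(lapply(seq_len(k), function(j) {
    idx <- which(cl == j)
    if (length(idx) < 2) return(idx)
    r <- vapply(idx, function(i) {
      suppressWarnings(stats::cor(features[i, ], cm[j, ]))
    }, numeric(1))
    r[!is.finite(r)] <- -Inf
    idx[order(r, decreasing = TRUE)]
  }))
  list(cluster_means = cm, normalized = norm01, order = ord,
       epoch_cols = attr(features, "epoch_cols"))
}

#' Anatomical concentration shuffle test along one axis
#'
#' Neurons are binned into `n_bins` equal-width bins along the chosen
#' axis; each bin's mean value, normalized by the summed absolute bin
#' means, gives the relative concentration profile; the statistic is the
#' SD of that profile, compared against value-shuffled nulls. For a
#' cluster, pass its membership indicator as `values`.
#'
#' @param values per-neuron scalar (coefficient or 0/1 indicator).
#' @param coords per-neuron positions along the axis (mm).
#' @param n_bins number of bins (8).
#' @param n_shuffle shuffles (10000).
#' @param seed RNG seed.
#' @return list of class `spatial_test`: `relative_concentration`,
#'   `bin_edges`, `bin_means`, `statistic`, `p_value`.
#' @export
spatial_concentration_test <- function(values, coords, n_bins = 8,
                                       n_shuffle = 10000, seed = 1L) {
  ok <- is.finite(values) & is.finite(coords)
  values <- values[ok]; coords <- coords[ok]
  if (length(values) < n_bins) stop("need at least n_bins neurons")
  edges <- seq(min(coords), max(coords), length.out = n_bins + 1)
  bin <- findInterval(coords, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  if (any(counts == 0)) {
    message("spatial test: ", sum(counts == 0),
            " empty bin(s) contribute zero concentration")
  }
  B <- matrix(0, n_bins, length(values))
  B[cbind(bin, seq_along(values))] <- 1
  denom <- pmax(counts, 1)
  conc_of <- function(V) {
    bm <- (B %*% V) / denom             # bin means (n_bins x cols)
    tot <- colSums(abs(bm))
    tot[tot == 0] <- 1
    sweep(bm, 2, tot, "/")
  }
  obs_conc <- drop(conc_of(cbind(values)))
  obs_stat <- stats::sd(obs_conc)
  set.seed(seed)
  Vs <- vapply(seq_len(n_shuffle), function(s) sample(values),
               numeric(length(values)))
  null_conc <- conc_of(Vs)
  null_stat <- apply(null_conc, 2, stats::sd)
  p <- mean(null_stat >= obs_stat)
  if (p == 0) p <- 1 / n_shuffle
  structure(list(relative_concentration = obs_conc, bin_edges = edges,
                 bin_means = drop((B %*% cbind(values)) / denom),
                 statistic = obs_stat, p_value = p,
                 n_shuffle = n_shuffle),
            class = "spatial_test")
}

#' Run the concentration test across axes (and values) with correction
#'
#' @param value_list named list of per-neuron value vectors (e.g. one per
#'   cluster or coefficient).
#' @param coords data.frame with `ap_mm`, `ml_mm`, `dv_mm`.
#' @param axes which axes to test.
#' @param n_bins,n_shuffle,seed forwarded to
#'   [spatial_concentration_test()].
#' @return data.frame with one row per value x axis, raw and
#'   Holm-Bonferroni corrected p-values across the whole family.
#' @export
spatial_test_family <- function(value_list, coords,
                                axes = c("AP", "ML", "DV"), n_bins = 8,
                                n_shuffle = 10000, seed = 1L) {
  axis_col <- c(AP = "ap_mm", ML = "ml_mm", DV = "dv_mm")
  rows <- list()
  i <- 0L
  for (vn in names(value_list)) {
    for (ax in axes) {
      i <- i + 1L
      st <- spatial_concentration_test(value_list[[vn]],
                                       coords[[axis_col[[ax]]]],
                                       n_bins, n_shuffle,
                                       seed = seed + i)
      rows[[i]] <- data.frame(value = vn, axis = ax,
                              statistic = st$statistic,
                              p_value = st$p_value)
    }
  }
  out <- do.call(rbind, rows)
  out$corrected_p <- stats::p.adjust(out$p_value, method = "holm")
  out
}
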