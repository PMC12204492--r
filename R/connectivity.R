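#' Per-subject input proportions
#'
#' Divides each subject's region counts by its total; zero-total
#' subjects are excluded.
#'
#' @param x `input_count_matrix` or a bare counts matrix
#'   (subjects x regions).
#' @return list with `props` (rows sum to 1), `subtype` (when available),
#'   `excluded` (row indices dropped).
#' @export
input_proportions <- function(x) {
  counts <- if (inherits(x, "input_count_matrix")) x$counts else as.matrix(x)
  subtype <- if (inherits(x, "input_count_matrix")) x$subtype else NULL
  tot <- rowSums(counts)
  excl <- which(tot == 0)
  if (length(excl)) {
    message("input_proportions: excluded zero-total subjects: ",
            paste(excl, collapse = ", "))
    counts <- counts[-excl, , drop = FALSE]
    if (!is.null(subtype)) subtype <- subtype[-excl]
    tot <- tot[-excl]
  }
  list(props = sweep(counts, 1, tot, "/"), subtype = subtype,
       excluded = excl)
}

#' Per-region one-way ANOVA across subtypes with BH correction
#'
#' For every region: one-way ANOVA of the proportion on subtype, with F,
#' p, eta-squared effect size; Benjamini-Hochberg adjustment across
#' regions; Tukey HSD pairwise comparisons where the adjusted p passes
#' `alpha`.
#'
#' @param props subjects x regions proportion matrix.
#' @param subtype per-subject group labels.
#' @param alpha significance level for post-hoc testing (0.05).
#' @return list with `table` (per-region data.frame) and `tukey` (named
#'   list of pairwise tables for significant regions).
#' @export
region_anova <- function(props, subtype, alpha = 0.05) {
  subtype <- as.factor(subtype)
  if (nlevels(subtype) < 2) stop("need at least two subtypes")
  if (min(table(subtype)) < 2) stop("need at least two subjects per subtype")
  rows <- lapply(colnames(props), function(rg) {
    y <- props[, rg]
    if (all(tapply(y, subtype, stats::var) == 0)) {
      return(data.frame(region = rg, F = NA_real_, p = NA_real_,
                        eta_sq = NA_real_, flagged = TRUE))
    }
    fit <- stats::aov(y ~ subtype)
    sm <- summary(fit)[[1]]
    data.frame(region = rg, F = sm$`F value`[1], p = sm$`Pr(>F)`[1],
               eta_sq = sm$`Sum Sq`[1] / sum(sm$`Sum Sq`), flagged = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  ok <- !tab$flagged
  tab$p_adj[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  tukey <- list()
  for (rg in tab$region[ok & tab$p_adj < alpha]) {
    tk <- stats::TukeyHSD(stats::aov(props[, rg] ~ subtype))$subtype
    tukey[[rg]] <- data.frame(pair = rownames(tk), tk, row.names = NULL)
  }
  list(table = tab, tukey = tukey)
}

#' Connectivity PCA with pairwise similarity and permutation tests
#'
#' Proportions are z-scored per region and reduced to the first `n_pcs`
#' principal components. For each group pair: two-sample t-tests on each
#' PC combined by Fisher's method; the mean cross-group Euclidean
#' distance in PC space converted to a similarity index `1/(1+d)`; a
#' permutation p from random group reassignment. Group mean PC vectors
#' feed an average-linkage dendrogram.
#'
#' @param props subjects x regions proportion matrix.
#' @param subtype per-subject group labels.
#' @param n_pcs retained components (3).
#' @param n_perm permutations (1000).
#' @param seed RNG seed.
#' @return list with `scores`, `similarity`, `perm_p`, `fisher_p`
#'   (pairwise matrices), `dendrogram` (hclust), `explained_variance_ratio`.
#' @export
connectivity_pca_similarity <- function(props, subtype, n_pcs = 3,
                                        n_perm = 1000, seed = 1L) {
  subtype <- as.factor(subtype)
  Z <- scale(props)
  Z[, apply(props, 2, stats::sd) == 0] <- 0
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  S <- pc$x[, seq_len(n_pcs), drop = FALSE]
  gl <- levels(subtype)
  ng <- length(gl)
  sim <- matrix(NA_real_, ng, ng, dimnames = list(gl, gl))
  pperm <- fish <- sim
  mean_cross_dist <- function(A, B) {
    mean(as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                             nrow(A) + seq_len(nrow(B))])
  }
  set.seed(seed)
  for (i in seq_len(ng)) {
    sim[i, i] <- 1
    for (j in seq_len(ng)) {
      if (j <= i) next
      ai <- subtype == gl[i]; aj <- subtype == gl[j]
      A <- S[ai, , drop = FALSE]; B <- S[aj, , drop = FALSE]
      d_obs <- mean_cross_dist(A, B)
      sim[i, j] <- sim[j, i] <- 1 / (1 + d_obs)
      if (nrow(A) > 1 && nrow(B) > 1) {
        pvals <- vapply(seq_len(n_pcs), function(k) {
          stats::t.test(A[, k], B[, k])$p.value
        }, numeric(1))
        stat <- -2 * sum(log(pvals))
        fish[i, j] <- fish[j, i] <-
          stats::pchisq(stat, df = 2 * n_pcs, lower.tail = FALSE)
      }
      pool <- rbind(A, B); nA <- nrow(A)
      null_d <- vapply(seq_len(n_perm), function(p_) {
        idx <- sample.int(nrow(pool), nA)
        mean_cross_dist(pool[idx, , drop = FALSE],
                        pool[-idx, , drop = FALSE])
      }, numeric(1))
      pperm[i, j] <- pperm[j, i] <-
        (1 + sum(null_d >= d_obs)) / (1 + n_perm)
    }
  }
  gm <- t(vapply(gl, function(g) colMeans(S[subtype == g, , drop = FALSE]),
                 numeric(n_pcs)))
  dnd <- stats::hclust(stats::dist(gm), method = "average")
  list(scores = S, similarity = sim, perm_p = pperm, fisher_p = fish,
       dendrogram = dnd,
       explained_variance_ratio = pc$sdev^2 / sum(pc$sdev^2))
}

#' Linear-SVM subtype decoder on standardized input proportions
#'
#' Multiclass linear SVM (one-vs-one), scored by leave-one-subject-out
#' cross-validation; a bootstrap accuracy distribution (resampling
#' subjects with replacement, testing on the full dataset) and a
#' label-shuffle permutation p-value (add-one convention) accompany it.
#' Significance is declared when the observed accuracy exceeds the 95th
#' percentile of the null.
#'
#' @param props subjects x regions proportion matrix.
#' @param subtype per-subject group labels.
#' @param n_boot bootstrap iterations (1000).
#' @param n_perm label shuffles (1000).
#' @param cost SVM regularization (1).
#' @param seed RNG seed.
#' @return list with `loocv_accuracy`, `boot_accuracies`,
#'   `null_accuracies`, `perm_p`, `significant`, `confusion`
#'   (LOOCV confusion matrix).
#' @export
subtype_decoder <- function(props, subtype, n_boot = 1000, n_perm = 1000,
                            cost = 1, seed = 1L) {
  y <- droplevels(as.factor(subtype))
  if (nlevels(y) < 2) stop("need at least two groups")
  if (min(table(y)) < 2) {
    warning("a group has a single subject; its LOOCV fold is degenerate")
  }
  Z <- scale(props)
  Z[, !is.finite(colSums(Z))] <- 0
  loocv <- function(X, yy) {
    pred <- factor(rep(NA, length(yy)), levels = levels(yy))
    for (i in seq_along(yy)) {
      if (length(unique(yy[-i])) < 2) next
      fit <- e1071::svm(X[-i, , drop = FALSE], droplevels(yy[-i]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred[i] <- as.character(stats::predict(fit, X[i, , drop = FALSE]))
    }
    pred
  }
  pred <- loocv(Z, y)
  acc <- mean(pred == y, na.rm = TRUE)
  confusion <- table(truth = y, predicted = pred)
  set.seed(seed)
  boot_acc <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(Z), replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    fit <- e1071::svm(Z[idx, , drop = FALSE], droplevels(y[idx]),
                      kernel = "linear", cost = cost, scale = FALSE)
    mean(as.character(stats::predict(fit, Z)) == as.character(y))
  }, numeric(1))
  null_acc <- vapply(seq_len(n_perm), function(p_) {
    ys <- sample(y)
    mean(loocv(Z, ys) == ys, na.rm = TRUE)
  }, numeric(1))
  perm_p <- (1 + sum(null_acc >= acc)) / (1 + n_perm)
  list(loocv_accuracy = acc, boot_accuracies = boot_acc,
       null_accuracies = null_acc, perm_p = perm_p,
       significant = acc > stats::quantile(null_acc, 0.95, names = FALSE),
       confusion = confusion)
}
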