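test_that("input proportions normalize rows and drop empty subjects", {
  m <- rbind(c(2, 2), c(5, 0), c(0, 0))
  colnames(m) <- c("CA1", "SuM")
  expect_message(pr <- input_proportions(m), "excluded")
  expect_equal(unname(pr$props[1, ]), c(0.5, 0.5))
  expect_equal(unname(pr$props[2, ]), c(1, 0))
  expect_equal(pr$excluded, 3)
  set.seed(1)
  icm <- generate_input_counts(3, default_region_profiles(), 50, 1000,
                               seed = 1)
  pp <- input_proportions(icm)
  expect_equal(unname(rowSums(pp$props)), rep(1, nrow(pp$props)),
               tolerance = 1e-12)
})

test_that("two-group region ANOVA equals the squared t statistic", {
  set.seed(2)
  props <- matrix(runif(10 * 3, 0.2, 0.4), 10)
  colnames(props) <- c("CA1", "SuM", "LHA")
  props <- props / rowSums(props)
  grp <- rep(c("Glp1r", "Chat"), each = 5)
  an <- region_anova(props, grp)
  for (rg in colnames(props)) {
    tt <- t.test(props[grp == "Glp1r", rg], props[grp == "Chat", rg],
                 var.equal = TRUE)
    row <- an$table[an$table$region == rg, ]
    expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
  # BH monotonicity
  ord <- order(an$table$p)
  expect_true(all(diff(an$table$p_adj[ord]) >= -1e-12))
  expect_true(all(an$table$p_adj >= an$table$p - 1e-12))
})

test_that("a planted single-region difference is isolated after FDR", {
  prof <- default_region_profiles()[c("Glp1r", "Chat")]
  prof$Chat <- prof$Glp1r
  prof$Chat["SuM"] <- prof$Chat["SuM"] + 0.25
  prof$Chat <- prof$Chat / sum(prof$Chat)
  icm <- generate_input_counts(8, prof, concentration = 4000,
                               total_cells = 4000, seed = 3)
  pr <- input_proportions(icm)
  an <- region_anova(pr$props, pr$subtype)
  sig <- an$table$region[!is.na(an$table$p_adj) & an$table$p_adj < 0.05]
  expect_true("SuM" %in% sig)
  # the diluted non-SuM proportions shift together; the planted region
  # must carry the dominant effect
  expect_equal(an$table$region[which.max(an$table$F)], "SuM")
  expect_true("SuM" %in% names(an$tukey))
})

test_that("similarity index follows 1/(1+d) and its PCA is well-formed", {
  set.seed(4)
  icm <- generate_input_counts(5, default_region_profiles(), 60, 2000,
                               seed = 4)
  pr <- input_proportions(icm)
  out <- connectivity_pca_similarity(pr$props, pr$subtype, n_perm = 100,
                                     seed = 1)
  expect_true(all(out$similarity > 0 & out$similarity <= 1))
  expect_true(isSymmetric(out$similarity))
  expect_equal(unname(diag(out$similarity)), rep(1, 4))
  expect_s3_class(out$dendrogram, "hclust")
  # formula spot checks
  expect_equal(1 / (1 + 0), 1)
  expect_equal(1 / (1 + 1), 0.5)
  # Fisher combination is chi-squared distributed under the null
  set.seed(5)
  stats_null <- replicate(400, -2 * sum(log(runif(3))))
  expect_gt(ks.test(stats_null, pchisq, df = 6)$p.value, 0.01)
})

test_that("identical profiles yield uniform permutation p-values and chance decoding", {
  prof <- default_region_profiles()
  for (s_ in names(prof)) prof[[s_]] <- prof$Glp1r
  icm <- generate_input_counts(5, prof, concentration = 40,
                               total_cells = 1500, seed = 6)
  pr <- input_proportions(icm)
  out <- connectivity_pca_similarity(pr$props, pr$subtype, n_perm = 200,
                                     seed = 2)
  ps <- out$perm_p[upper.tri(out$perm_p)]
  expect_gt(min(ps), 0.01)
  dec <- subtype_decoder(pr$props, pr$subtype, n_boot = 50, n_perm = 100,
                         seed = 3)
  expect_false(dec$significant)
  expect_gt(dec$perm_p, 0.05)
})

test_that("separable profiles give perfect LOOCV and the smallest possible p", {
  icm <- generate_input_counts(5, default_region_profiles(),
                               concentration = 1e6, total_cells = 4000,
                               seed = 7)
  pr <- input_proportions(icm)
  dec <- subtype_decoder(pr$props, pr$subtype, n_boot = 50, n_perm = 99,
                         seed = 4)
  expect_equal(dec$loocv_accuracy, 1.0)
  expect_equal(dec$perm_p, 1 / 100)
  expect_true(dec$significant)
  # confusion rows sum to per-class counts
  expect_equal(unname(rowSums(dec$confusion)),
               unname(as.integer(table(pr$subtype))))
})
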