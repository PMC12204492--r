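#!/usr/bin/env Rscript
# Rabies-tracing input statistics: per-region ANOVA across subtypes with
# BH correction and Tukey post hocs, PCA with similarity indices and
# permutation tests, and a subtype decoder on standardized proportions.

library(avoidpop)

out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

counts <- read.csv("results/data/input_counts.csv", check.names = FALSE)
icm <- structure(list(counts = as.matrix(counts[, -(1:2)]),
                      subtype = counts$subtype,
                      region_names = colnames(counts)[-(1:2)]),
                 class = "input_count_matrix")
pr <- input_proportions(icm)

an <- region_anova(pr$props, pr$subtype)
write.csv(an$table, file.path(out, "region_anova.csv"), row.names = FALSE)
message("regions differing between subtypes (BH-adjusted p < 0.05):")
print(an$table[!is.na(an$table$p_adj) & an$table$p_adj < 0.05,
               c("region", "F", "p_adj", "eta_sq")])

pca <- connectivity_pca_similarity(pr$props, pr$subtype, n_perm = 1000,
                                   seed = seed)
write.csv(as.data.frame(pca$similarity),
          file.path(out, "similarity_matrix.csv"))
message("pairwise similarity indices (1/(1+d) in PC space):")
print(round(pca$similarity, 3))

dec <- subtype_decoder(pr$props, pr$subtype, n_boot = 1000, n_perm = 1000,
                       seed = seed)
message(sprintf("subtype decoder: LOOCV accuracy %.2f, permutation p = %.4g (%s)",
                dec$loocv_accuracy, dec$perm_p,
                if (dec$significant) "significant" else "not significant"))
write.csv(as.data.frame(dec$confusion),
          file.path(out, "decoder_confusion.csv"), row.names = FALSE)
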