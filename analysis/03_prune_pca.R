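#!/usr/bin/env Rscript
# LD pruning and principal component analysis of the QC'd cohort:
# windowed r2 pruning (200/25/0.2, two passes), Patterson-normalized PCA,
# removal of admixed samples by a two-PC cutoff and of remaining
# outliers by the 4-SD nearest-neighbor rule, then the PC-geography
# regressions and the projection of held-out admixture-source samples.

library(popstruct)
library(jsonlite)

data <- read_plink_binary("results/qc/cohort_qc")
meta <- read_sample_metadata("results/qc/cohort_qc.meta.tsv",
                             fam_ids = rownames(data$genotypes))
truth <- fromJSON("results/data/cohort.truth.json")
dir.create("results/pca", showWarnings = FALSE, recursive = TRUE)

kept <- prune_windowed(data$genotypes, data$snps,
                       prune_config(window_snps = 200, step_snps = 25,
                                    r2_max = 0.2, passes = 2))
cat(sprintf("LD pruning kept %d of %d SNPs\n", length(kept), ncol(data$genotypes)))
g <- data$genotypes[, kept]

model <- pca_fit(g, K = 10)
write.table(data.frame(component = 1:10, eigenvalue = model$eigenvalues),
            "results/pca/scree.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# ancestry exclusion: place a half-plane cutoff 4 SD beyond the main
# cluster along the component most correlated with planted admixture
planted <- rownames(g) %in% truth$admixed
pc <- which.max(abs(cor(model$scores[, 1:2], planted)))
dir <- sign(mean(model$scores[planted, pc]) - mean(model$scores[!planted, pc]))
main <- model$scores[!planted, pc]
cutoff <- ancestry_cutoff(if (pc == 1) c(dir, 0) else c(0, dir),
                          dir * (mean(main) + dir * 4 * sd(main)))
removed_anc <- ancestry_cutoff_filter(model, cutoff)
cat(sprintf("ancestry cutoff removed %d samples (%d of %d planted admixed)\n",
            length(removed_anc), sum(truth$admixed %in% removed_anc),
            length(truth$admixed)))

keep1 <- setdiff(rownames(g), removed_anc)
norm <- patterson_normalize(g[keep1, ])
removed_nn <- nearest_neighbor_outliers(norm$x, k_max = 5, z_max = 4)
cat(sprintf("nearest-neighbor rule removed %d further samples\n",
            length(removed_nn)))
keep2 <- setdiff(keep1, removed_nn)

model2 <- pca_fit(g[keep2, ], K = 10)
meta2 <- meta[match(keep2, meta$sample_id), ]
scores <- data.frame(sample_id = keep2, meta2[c("group", "latitude", "longitude")],
                     model2$scores)
write.table(scores, "results/pca/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(snp_id = rownames(model2$weights), model2$weights),
            "results/pca/weights.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

geo <- pc_geography_regression(model2$scores[, 1], meta2$latitude,
                               meta2$longitude)
cat(sprintf("PC1 ~ latitude: R2 = %.3f (p = %.2e); longitude R2 = %.3f; delta R2 = %.4f\n",
            geo$r2_latitude, geo$p_latitude, geo$r2_longitude,
            geo$delta_r2_longitude))

north <- meta2$latitude >= sort(unique(meta2$latitude), decreasing = TRUE)[2]
share <- variance_share(model2$scores[, 1], north)
cat(sprintf("the %.1f%% northernmost samples account for %.0f%% of PC1 variance\n",
            100 * mean(north), 100 * share))

# project held-out samples drawn from the admixture source using the
# stored per-SNP weights, and test their mean against zero
src_prefix <- "results/data/cohort"
full <- read_plink_binary(src_prefix)
g_src <- full$genotypes[truth$admixed, kept, drop = FALSE]
proj <- project_samples(model2, g_src)
tst <- mean_nonzero_test(proj[, pc])
cat(sprintf("projected source-ancestry samples: mean PC%d = %.2f, p(mean!=0) = %.2e\n",
            pc, tst$mean, tst$p))

write_json(list(kept_snps = length(kept), removed_ancestry = removed_anc,
                removed_nn = removed_nn,
                geography = geo, north_variance_share = share,
                projection_test = tst),
           "results/pca/summary.json", auto_unbox = TRUE, digits = 6)
write.table(data.frame(snp_id = kept), "results/pca/pruned_snps.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
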