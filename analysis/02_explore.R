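#!/usr/bin/env Rscript
# Unsupervised structure in the benchmark spectra: replicate averaging,
# the full preprocessing chain (Savitzky-Golay 13/2, linear-endpoint
# baseline, per-spectrum min-max, global mean-centering), then PCA scores/
# loadings and an HCA dendrogram per modality. The two genera should form
# two clean groups (top-split purity 1.0) before any supervised modelling.
# Reads results/data/, writes results/exploratory/.

library(chemodisc)

out <- "results/exploratory"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (modality in c("uv", "ftir")) {
  ds <- read_dataset(sprintf("results/data/%s.csv", modality), modality)
  samples <- average_replicates(ds)
  pre <- preprocess_dataset(samples, preprocess_config())$dataset
  pc <- pca(pre$intensities, k = 2L)
  dendro <- hca(pre)
  purity <- two_group_separation(dendro, pre$classes)

  write.csv(data.frame(sample_id = pre$sample_ids, class = pre$classes,
                       PC1 = pc$scores[, 1], PC2 = pc$scores[, 2]),
            file.path(out, sprintf("pca_scores_%s.csv", modality)),
            row.names = FALSE)
  write.csv(data.frame(axis = pre$axis, PC1 = pc$loadings[, 1],
                       PC2 = pc$loadings[, 2]),
            file.path(out, sprintf("pca_loadings_%s.csv", modality)),
            row.names = FALSE)
  dendrogram_newick(dendro,
                    file.path(out, sprintf("dendrogram_%s.nwk", modality)))
  message(sprintf(
    "%s: PC1 %.2f%%, PC2 %.2f%% of variance; HCA (%s) two-group purity %.3f",
    modality, pc$explained_variance_ratio[1], pc$explained_variance_ratio[2],
    dendro$linkage, purity))
}
message("exploratory tables written to ", out)
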