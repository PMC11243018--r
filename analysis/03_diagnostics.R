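#!/usr/bin/env Rscript
# Stage 3 -- unsupervised diagnostics.
#
# PCA score plot data with the 95% Hotelling ellipse (QC injections should
# gather tightly; concentration groups should separate along PC1) and
# Ward hierarchical clustering of the spiked samples cut at k = 3.

library(svmscreen)

filt <- read_feature_table("results/data/calibrated_filtered.tsv")

xall <- scale_matrix(t(filt$intensity), "uv")
pm <- pca(xall, 2)
scores <- data.frame(sample_id = filt$samples$sample_id,
                     group = filt$samples$group, pm$scores)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PCA: R2X = %.2f / %.2f; Hotelling ellipse a = %.1f, b = %.1f",
                pm$r2x[1], pm$r2x[2], pm$ellipse$a, pm$ellipse$b))

spiked <- filt$samples$type == "sample"
hc <- hcluster(scale_matrix(t(filt$intensity[, spiked]), "uv"), k = 3)
ari <- e1071::classAgreement(table(hc$labels,
                                   filt$samples$group[spiked]))$crand
write.table(data.frame(sample_id = filt$samples$sample_id[spiked],
                       group = filt$samples$group[spiked],
                       cluster = hc$labels),
            "results/hca_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "HCA (Ward, k = 3): adjusted Rand index vs concentration groups = %.3f",
  ari))
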