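#!/usr/bin/env Rscript
# Stage 1 -- simulate the spiked-maize study design.
#
# Generates the default synthetic dataset: 124 library compounds spiked at
# 20/50/100 ng/mL in nonuplicate plus 12 pooled-QC injections, 1289
# correlated background features, 34 erratic features and the two
# deuterated internal standards; also a blank (background-only) dataset
# used later for the false-positive check.

library(svmscreen)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cfg <- synthetic_config(seed = seed)
ds <- generate_spiked_dataset(cfg, pvd_library())
write_feature_table(ds$table, "results/data/feature_table.tsv")
write.table(ds$truth$marker_map, "results/data/ground_truth_markers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$recoveries, "results/data/ground_truth_recoveries.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

blank <- generate_spiked_dataset(
  synthetic_config(seed = seed + 1, n_markers = 0, n_background = 400,
                   n_erratic = 20))
write_feature_table(blank$table, "results/data/blank_table.tsv")

message(sprintf(
  "simulated %d x %d spiked table (%d markers, %d background, %d erratic) and a %d-variable blank",
  nrow(ds$table$intensity), ncol(ds$table$intensity), cfg$n_markers,
  cfg$n_background, cfg$n_erratic, nrow(blank$table$intensity)))
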