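#!/usr/bin/env Rscript
# Stage 4 -- supervised modelling of the two one-vs-rest contrasts.
#
# For 20-vs-rest ("low") and 100-vs-rest ("high"): SMOTE balances the
# 9-vs-18 design to 18-vs-18; OPLS-DA (1 predictive + 1 orthogonal
# component) is validated by a 200-iteration permutation test and yields
# the VIP > 1 candidate list and S-plot statistics; an RBF SVM is tuned on
# a powers-of-two (c, g) grid by 3-fold CV, its 10 x 10-fold accuracy is
# reported, and SVM-RFE produces the weight-squared ranking from which the
# VIP-constrained prefix is retained.

library(svmscreen)

filt <- read_feature_table("results/data/calibrated_filtered.tsv")
seed <- 1L

spiked <- which(filt$samples$type == "sample")
cand <- !filt$variables$is_istd
x <- t(filt$intensity[cand, spiked])
grp <- filt$samples$group[spiked]

for (contrast in c(low = "20", high = "100")) {
  lab <- names(which(c(low = "20", high = "100") == contrast))
  y <- ifelse(grp == contrast, "one", "rest")
  bal <- smote_balance(x, y, k = 5, seed = seed + 20)
  xs <- scale_matrix(bal$x, "uv")

  model <- oplsda_fit(xs, bal$y, n_orthogonal = 1, cv_folds = 7)
  perm <- permutation_test(xs, bal$y, n_iter = 200, seed = seed + 30)
  message(sprintf(
    "%s-vs-rest: R2Y = %.3f, Q2 = %.3f; intercepts R2Y %.3f / Q2Y %.3f, p = %.4f (%s)",
    lab, model$r2y, model$q2, perm$r2_intercept, perm$q2_intercept,
    perm$p_value, if (perm$valid) "valid" else "INVALID"))

  vip_ids <- model$variable_ids[model$vip > 1]
  write.table(cbind(splot(model), vip = model$vip),
              sprintf("results/opls_%s.tsv", lab),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(perm$iterations, sprintf("results/permutations_%s.tsv", lab),
              sep = "\t", quote = FALSE, row.names = FALSE)

  svm_xs <- scale_matrix(bal$x, "uv")$data
  tune <- grid_search_rbf(svm_xs, bal$y, folds = 3, seed = seed + 40)
  acc <- cv_accuracy(svm_xs, bal$y, tune$best_cost, tune$best_gamma,
                     folds = 10, repeats = 10, seed = seed + 50)
  wt <- svmrfe_rank(bal$x, bal$y, tune)
  pref <- retained_prefix(vip_ids, wt)
  message(sprintf(
    "%s-vs-rest SVM: (c, g) = (%.4g, %.4g); 10-fold accuracy %.1f%%; %d VIP > 1 in a %d-entry prefix (overlap %.1f%%)",
    lab, tune$best_cost, tune$best_gamma, acc, length(vip_ids),
    pref$prefix_length, pref$overlap_ratio))

  wt_out <- as.data.frame(wt)
  wt_out$in_prefix <- wt_out$variable_id %in% pref$prefix
  wt_out$vip_gt1 <- wt_out$variable_id %in% vip_ids
  write.table(wt_out, sprintf("results/weight_table_%s.tsv", lab),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
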