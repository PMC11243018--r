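fake_wt <- function(ids) {
  data.frame(variable_id = ids, w = rev(seq_along(ids)),
             w2 = rev(seq_along(ids))^2,
             elimination_rank = seq_along(ids),
             stringsAsFactors = FALSE)
}

test_that("the retained prefix is the smallest head covering every VIP variable", {
  wt <- fake_wt(paste0("V", 1:10))
  pref <- retained_prefix(c("V1", "V2", "V3"), wt)
  expect_equal(pref$prefix_length, 3)
  expect_equal(pref$prefix, c("V1", "V2", "V3"))

  pref2 <- retained_prefix(c("V2", "V7"), wt)
  expect_equal(pref2$prefix_length, 7)
  expect_true(all(c("V2", "V7") %in% pref2$prefix))

  expect_equal(retained_prefix(character(0), wt)$prefix_length, 0)
  expect_error(retained_prefix("V99", wt), "absent")
})

test_that("overlap ratios reproduce the printed set-size arithmetic", {
  # 228 VIP > 1 variables inside a 253-entry weight prefix -> 90.1%
  wt <- fake_wt(sprintf("V%03d", 1:300))
  vip <- c(sprintf("V%03d", 1:227), "V253")  # 228 ids, worst at rank 253
  pref <- retained_prefix(vip, wt)
  expect_equal(pref$prefix_length, 253)
  expect_equal(pref$overlap_ratio, 90.1)
  expect_equal(overlap_ratio(vip, pref$prefix), 90.1)

  # 188 VIP variables in a 214-entry prefix: 87.85%, printed as 87.8
  vip2 <- c(sprintf("V%03d", 1:187), "V214")
  pref2 <- retained_prefix(vip2, wt)
  expect_equal(pref2$prefix_length, 214)
  expect_equal(pref2$overlap_ratio, 87.9)  # round-half-up of 87.8504

  expect_equal(overlap_ratio(c("a", "b"), c("a", "b")), 100.0)
  expect_error(overlap_ratio("a", character(0)), "empty")
})

test_that("consensus candidates intersect the two retained prefixes", {
  wt <- fake_wt(paste0("V", 1:10))
  a <- retained_prefix(paste0("V", 1:4), wt)
  b <- retained_prefix(paste0("V", 3:6), wt)
  expect_setequal(consensus_candidates(a, b), paste0("V", 1:4))

  d1 <- retained_prefix("V2", fake_wt(c("V2", "V9")))
  d2 <- retained_prefix("V5", fake_wt(c("V5", "V7")))
  expect_equal(consensus_candidates(d1, d2), character(0))
  expect_setequal(consensus_candidates(a, a), a$prefix)
})

# a hand-built table: one row per case, n samples per group + 2 QC
stats_table <- function(values) {
  n_g <- length(values[[1]][[1]])
  samples <- data.frame(
    sample_id = c(paste0("s", 1:(3 * n_g)), "q1", "q2"),
    group = c(rep(c("20", "50", "100"), each = n_g), "QC", "QC"),
    type = c(rep("sample", 3 * n_g), "QC", "QC"))
  intensity <- do.call(rbind, lapply(values, function(v) {
    row <- c(v[[1]], v[[2]], v[[3]])
    c(row, mean(row), mean(row))
  }))
  vars <- data.frame(variable_id = paste0("X", seq_along(values)),
                     mz = 200 + seq_along(values), rt_min = 5,
                     is_istd = FALSE)
  feature_table(intensity, vars, samples)
}

test_that("pairwise Welch t-tests match the textbook computation", {
  tab <- stats_table(list(
    list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(9, 10, 11, 12)),
    list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))))
  p <- pairwise_ttests(tab)
  # (1,2,3,4) vs (5,6,7,8): t = 4.3818, two-sided p = 0.00466 (Welch df 6)
  expect_lt(abs(p$p_20vs50[1] - 2 * pt(-4.38178, 6)), 5e-6)
  # identical groups: t = 0, p = 1
  expect_equal(p$p_20vs50[2], 1)
  expect_false(any(p$degenerate))

  # constant identical groups are flagged degenerate with p = 1
  tabc <- stats_table(list(list(c(2, 2, 2, 2), c(2, 2, 2, 2),
                                c(3, 4, 5, 6))))
  expect_warning(pc <- pairwise_ttests(tabc), "zero variance")
  expect_equal(pc$p_20vs50[1], 1)
  expect_true(pc$degenerate[1])
})

test_that("fold changes are group-mean ratios against the lowest group", {
  tab <- stats_table(list(
    list(c(10, 10, 10, 10), c(25, 25, 25, 25), c(50, 50, 50, 50)),
    list(c(5, 5, 5, 5), c(5, 5, 5, 5), c(5, 5, 5, 5))))
  fc <- fold_changes(tab)
  expect_equal(fc$FC_50vs20[1], 2.5)
  expect_equal(fc$FC_100vs20[1], 5.0)
  expect_equal(fc$FC_50vs20[2], 1.0)
})

test_that("noise-free synthetic markers hit the theoretical fold changes exactly", {
  ds <- generate_spiked_dataset(noiseless_config(n_markers = 4,
                                                 n_background = 2,
                                                 n_erratic = 0))
  cal <- calibrate(ds$table, ds$truth$recoveries)
  fc <- fold_changes(cal, ds$truth$marker_map$variable_id)
  expect_equal(fc$FC_50vs20, rep(2.5, 4))
  expect_equal(fc$FC_100vs20, rep(5.0, 4))
})

test_that("eligibility requires every p below and every FC above threshold", {
  pv <- data.frame(variable_id = c("a", "b", "c", "d"),
                   p_20vs50 = c(0.01, 0.01, 0.01, 0.04),
                   p_20vs100 = c(0.01, 0.01, 0.01, 0.04),
                   p_50vs100 = c(0.01, 0.2, 0.01, 0.04))
  fc <- data.frame(variable_id = c("a", "b", "c", "d"),
                   FC_50vs20 = c(2.5, 2.5, 1.9, 2.1),
                   FC_100vs20 = c(5, 5, 5, 2.1))
  el <- confirm_eligible(c("a", "b", "c", "d"), pv, fc)
  expect_equal(el$eligible, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(el$reason[2], "p-value")
  expect_equal(el$reason[3], "fold-change")

  # monotone: improving any statistic never flips eligible -> ineligible
  pv2 <- pv; pv2$p_50vs100 <- pv$p_50vs100 / 2
  fc2 <- fc; fc2$FC_50vs20 <- fc$FC_50vs20 * 2
  el2 <- confirm_eligible(c("a", "b", "c", "d"), pv2, fc2)
  expect_true(all(el2$eligible >= el$eligible))
  expect_error(confirm_eligible("zz", pv, fc), "missing")
})
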