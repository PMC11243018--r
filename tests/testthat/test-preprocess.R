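test_that("internal-standard curve fitting recovers exact affine data", {
  fit <- fit_is_curve(data.frame(level = c(5, 10, 25, 50, 100),
                                 area = c(50, 100, 250, 500, 1000)))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  # closed-form OLS on exact affine data y = 10x + 5
  fit2 <- fit_is_curve(data.frame(level = c(5, 10, 25, 50, 100),
                                  area = c(55, 105, 255, 505, 1005)))
  expect_equal(fit2$slope, 10)
  expect_equal(fit2$intercept, 5)

  expect_error(fit_is_curve(data.frame(level = 5, area = 50)), "levels")
  expect_error(fit_is_curve(data.frame(level = c(5, 5), area = c(1, 2))),
               "levels")
})

test_that("recovery back-calculation is exact arithmetic", {
  fit <- list(slope = 10, intercept = 0)
  expect_equal(is_recovery(400, fit, 50), 80)
  expect_equal(is_recovery(500, fit, 50), 100)
  # (365.5 - 5) / 10 = 36.05; 100 * 36.05 / 50 = 72.1
  expect_equal(is_recovery(365.5, list(slope = 10, intercept = 5), 50),
               72.1)
  expect_error(is_recovery(400, fit, 0), "nominal")
  expect_error(is_recovery(400, list(slope = 0, intercept = 0), 50),
               "slope")
})

test_that("combined recovery is the harmonic mean of the two standards", {
  expect_equal(combined_recovery(80, 80), 80)
  expect_equal(combined_recovery(100, 100), 100)
  expect_equal(combined_recovery(75.6, 73.6), 74.59, tolerance = 0.01 / 74)
  # symmetric, and never above the arithmetic mean
  set.seed(1)
  r1 <- runif(50, 10, 120); r2 <- runif(50, 10, 120)
  expect_equal(combined_recovery(r1, r2), combined_recovery(r2, r1))
  expect_true(all(combined_recovery(r1, r2) <= (r1 + r2) / 2 + 1e-12))
  expect_error(combined_recovery(-5, 80), "positive")
})

test_that("calibration rescales each group to 100% mean recovery", {
  ds <- tiny_table(seed = 31)
  recs <- ds$truth$recoveries
  cal <- calibrate(ds$table, recs)
  for (g in c("20", "50", "100")) {
    k <- 100 / mean(recs$r_combined[recs$group == g])
    expect_equal(unname(cal$kappa[[g]]), k)
    idx <- ft_group_cols(ds$table, g)
    expect_equal(cal$intensity[, idx], ds$table$intensity[, idx] * k)
    # calibration preserves within-group intensity ratios
    ratio <- cal$intensity[1, idx] / cal$intensity[2, idx]
    expect_equal(ratio, ds$table$intensity[1, idx] /
                   ds$table$intensity[2, idx])
  }
  # QC columns get the mean group coefficient
  qc <- which(ds$table$samples$type == "QC")
  expect_equal(cal$intensity[, qc],
               ds$table$intensity[, qc] * mean(cal$kappa[c("20", "50", "100")]))
})

test_that("calibration handles flat and mixed recovery sets exactly", {
  ds <- generate_spiked_dataset(noiseless_config(n_markers = 2,
                                                 n_background = 2,
                                                 n_erratic = 0))
  recs <- ds$truth$recoveries  # all 100%
  cal <- calibrate(ds$table, recs)
  expect_equal(unname(cal$kappa), rep(1, 4))
  expect_equal(cal$intensity, ds$table$intensity)

  recs$r_combined <- rep(80, nrow(recs))
  cal80 <- calibrate(ds$table, recs)
  expect_equal(unname(cal80$kappa[["20"]]), 1.25)
  expect_equal(cal80$intensity[1, 1], ds$table$intensity[1, 1] * 1.25)

  # mean-then-reciprocal: group-mean recovery 80 -> kappa = 100/80
  recs$r_combined[recs$group == "20"] <-
    c(75, 85, 75, 85, 75, 85, 75, 85, 80)
  expect_equal(unname(calibrate(ds$table, recs)$kappa[["20"]]), 1.25)

  expect_error(calibrate(ds$table, recs[-1, ]), recs$sample_id[1])
})

test_that("RSD filter applies a strict per-group threshold", {
  ds <- tiny_table(seed = 41, n_qc = 3)
  cal <- calibrate(ds$table, ds$truth$recoveries)

  # plant one variable with QC values (10, 20, 30): QC RSD = 50%, dropped
  bad <- cal
  qc <- which(bad$samples$type == "QC")
  bad$intensity[1, ] <- 10
  bad$intensity[1, qc] <- c(10, 20, 30)
  filt <- rsd_filter(bad, threshold = 30)
  dropped <- bad$variables$variable_id[1]
  expect_false(dropped %in% filt$variables$variable_id)
  rep1 <- filt$filter_report[filt$filter_report$variable_id == dropped, ]
  expect_equal(rep1$rsd_QC, 50)

  # constant variable: RSD 0 everywhere, kept
  bad$intensity[2, ] <- 10
  expect_true(bad$variables$variable_id[2] %in%
                rsd_filter(bad, 30)$variables$variable_id)

  # strict inequality at the boundary: worst-group RSD 29.9% stays
  bad$intensity[3, ] <- 10
  bad$intensity[3, qc] <- c(7.01, 10, 12.99)  # mean 10, sd 2.99
  f3 <- rsd_filter(bad, 30)
  expect_true(bad$variables$variable_id[3] %in%
                f3$variables$variable_id)
  rep3 <- f3$filter_report[f3$filter_report$variable_id ==
                             bad$variables$variable_id[3], ]
  expect_equal(rep3$rsd_QC, 29.9)
})

test_that("RSD filtering is idempotent, subsetting, and spares noise-free markers", {
  ds <- tiny_table(seed = 51)
  cal <- calibrate(ds$table, ds$truth$recoveries)
  f1 <- rsd_filter(cal)
  expect_true(all(f1$variables$variable_id %in%
                    cal$variables$variable_id))
  f2 <- rsd_filter(f1)
  expect_identical(f2$variables$variable_id, f1$variables$variable_id)

  ds0 <- generate_spiked_dataset(noiseless_config(n_markers = 5,
                                                  n_background = 3,
                                                  n_erratic = 0))
  cal0 <- calibrate(ds0$table, ds0$truth$recoveries)
  kept <- rsd_filter(cal0)$variables$variable_id
  expect_true(all(ds0$truth$marker_map$variable_id %in% kept))
})

test_that("recovery records computed from IS features match the ground truth", {
  cfg <- synthetic_config(seed = 61, n_markers = 2, n_background = 2,
                          n_erratic = 0, intensity_cv = 0)
  ds <- generate_spiked_dataset(cfg)
  f1 <- list(slope = cfg$is_slope[1], intercept = cfg$is_intercept[1])
  f2 <- list(slope = cfg$is_slope[2], intercept = cfg$is_intercept[2])
  recs <- recovery_records(ds$table, f1, f2, cfg$is_nominal)
  expect_equal(recs$r_is1, ds$truth$recoveries$r_is1, tolerance = 1e-10)
  expect_equal(recs$r_combined, ds$truth$recoveries$r_combined,
               tolerance = 1e-10)
})
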