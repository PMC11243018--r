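test_that("generated compound libraries have the right size, ranges and determinism", {
  lib <- generate_compound_library(69, 55, seed = 3)
  expect_equal(nrow(lib), 124)
  expect_false(anyDuplicated(lib$name) > 0)
  expect_true(all(lib$exact_mass >= 100 & lib$exact_mass <= 1000))
  expect_true(all(lib$rt_min >= 2 & lib$rt_min <= 12))
  expect_true(all(lib$category %in% c("insecticide", "bactericide",
                                      "herbicide", "growth regulator",
                                      "sulfamido", "nitroimidazoles",
                                      "quinolones", "vermifuge",
                                      "tetracyclines", "macrolides")))
  # masses must be separated enough for unambiguous ppm matching
  expect_true(min(diff(sort(lib$exact_mass))) > 0.01)

  expect_equal(nrow(generate_compound_library(0, 0, seed = 1)), 0)
  expect_identical(generate_compound_library(2, 3, seed = 7),
                   generate_compound_library(2, 3, seed = 7))
  expect_error(generate_compound_library(-1, 3), "counts")
})

test_that("spiked dataset has the 3 x 9 + 12 column design and IS features", {
  ds <- tiny_table()
  expect_equal(ncol(ds$table$intensity), 3 * 9 + 12)
  expect_equal(sum(ds$table$samples$group == "QC"), 12)
  expect_equal(sum(ds$table$variables$is_istd), 2)
  expect_equal(nrow(ds$table$intensity), 3 + 4 + 2)
})

test_that("noise-free marker fold changes equal the theoretical concentration ratios", {
  ds <- generate_spiked_dataset(noiseless_config(n_markers = 5,
                                                 n_background = 3,
                                                 n_erratic = 0))
  x <- ds$table$intensity
  mk <- match(ds$truth$marker_map$variable_id,
              ds$table$variables$variable_id)
  g <- function(lvl) which(ds$table$samples$group == lvl)
  for (j in mk) {
    expect_equal(mean(x[j, g("50")]) / mean(x[j, g("20")]), 2.5)
    expect_equal(mean(x[j, g("100")]) / mean(x[j, g("20")]), 5.0)
    # within-group, noise-free intensities are constant
    expect_equal(sd(x[j, g("20")]), 0)
  }
  # background means are group-independent without drift
  bg <- match(ds$truth$background_ids, ds$table$variables$variable_id)
  expect_equal(x[bg, g("50")], x[bg, g("20")], ignore_attr = TRUE)
})

test_that("variable ids follow the M{mz}T{seconds} dialect", {
  # library mass 320.14050 at RT 6.37 min with zero jitter -> M320T382
  lib <- data.frame(no = 1, name = "norfloxacin", category = "quinolones",
                    exact_mass = 320.14050, rt_min = 6.37)
  cfg <- noiseless_config(n_markers = 1, n_background = 0, n_erratic = 0)
  ds <- generate_spiked_dataset(cfg, lib)
  expect_equal(ds$truth$marker_map$variable_id, "M320T382")
})

test_that("ground-truth id sets partition the non-IS variables", {
  ds <- tiny_table(n_markers = 4, n_background = 6, n_erratic = 3)
  tr <- ds$truth
  sets <- list(tr$marker_map$variable_id, tr$background_ids,
               tr$erratic_ids)
  expect_equal(sum(lengths(sets)), 13)
  expect_false(anyDuplicated(unlist(sets)) > 0)
  expect_setequal(c(unlist(sets), tr$istd_ids),
                  ds$table$variables$variable_id)
})

test_that("dataset generation is deterministic and validates inputs", {
  cfg <- synthetic_config(seed = 9, n_markers = 3, n_background = 5,
                          n_erratic = 1)
  d1 <- generate_spiked_dataset(cfg)
  d2 <- generate_spiked_dataset(cfg)
  expect_identical(d1$table$intensity, d2$table$intensity)
  expect_identical(d1$truth, d2$truth)

  expect_error(synthetic_config(n_markers = -1), "counts")
  expect_error(synthetic_config(group_levels = c(50, 20, 100)),
               "increasing")
  expect_error(synthetic_config(recovery_range_is1 = c(0, 90)),
               "recovery")
  expect_error(synthetic_config(intensity_cv = -0.1), "CV")
  small_lib <- generate_compound_library(2, 2, seed = 1)
  expect_error(generate_spiked_dataset(synthetic_config(n_markers = 5),
                                       small_lib), "library")
})

test_that("per-sample recoveries are drawn within the configured ranges", {
  ds <- tiny_table(seed = 21)
  r <- ds$truth$recoveries
  expect_true(all(r$r_is1 >= 72.9 & r$r_is1 <= 93.6))
  expect_true(all(r$r_is2 >= 72.9 & r$r_is2 <= 96.4))
  expect_equal(r$r_combined, 2 / (1 / r$r_is1 + 1 / r$r_is2))
})

test_that("internal-standard curves are exact lines without noise", {
  cd <- generate_is_curve(slope = 10, intercept = 0, noise_cv = 0)
  expect_equal(nrow(cd), 5)
  expect_equal(cd$area, c(50, 100, 250, 500, 1000))
  expect_identical(generate_is_curve(noise_cv = 0.1, seed = 4),
                   generate_is_curve(noise_cv = 0.1, seed = 4))
  expect_error(generate_is_curve(slope = 0), "slope")
  expect_error(generate_is_curve(nominal_levels = c(-5, 10)), "positive")
})

test_that("spiking arithmetic reproduces the study concentrations", {
  # 20 uL of a 1 ug/mL mix reconstituted to 1 mL -> 20 ng/mL
  expect_equal(spike_concentration(20, 1, 1), 20)
  expect_equal(spike_concentration(50, 1, 1), 50)
  expect_equal(spike_concentration(100, 1, 1), 100)
})

test_that("feature tables round-trip through TSV", {
  ds <- tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ds$table, path)
  back <- read_feature_table(path)
  expect_equal(back$intensity, ds$table$intensity, tolerance = 1e-12)
  expect_equal(back$samples$group, ds$table$samples$group)
  expect_equal(back$variables$mz, ds$table$variables$mz)
})
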