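test_that("ppm errors reproduce the published mass-error arithmetic", {
  expect_equal(ppm_error(500, 500), 0)
  # difenoconazole: observed 406.07130 vs reference 406.07197 -> -1.65 ppm
  expect_equal(ppm_error(406.07130, 406.07197), -1.654, tolerance = 0.05)
  # norfloxacin: 320.14194 vs 320.14050 -> +4.50 ppm
  expect_equal(ppm_error(320.14194, 320.14050), 4.507, tolerance = 0.05)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("recomputed mass errors of all published markers stay within tolerance", {
  mt <- marker_reference()
  lib <- pvd_library()
  expect_equal(nrow(mt), 120)
  expect_equal(nrow(lib), 124)
  err <- vapply(seq_len(nrow(mt)), function(i) {
    cand <- lib[tolower(lib$name) == tolower(mt$compound[i]), ]
    best <- which.min(abs(cand$exact_mass - mt$mz[i]))
    ppm_error(mt$mz[i], cand$exact_mass[best])
  }, numeric(1))
  # recomputation matches the printed column (rounded inputs: +-0.05 ppm)
  expect_true(all(abs(err - mt$mass_error_ppm) <= 0.05))
  expect_lte(max(abs(err)), 5)
})

test_that("marker matching applies both tolerances with ppm-first tie-breaks", {
  lib <- pvd_library()
  # norfloxacin as printed: observed (320.14194, 6.37) vs (320.14050, 6.51)
  eligible <- data.frame(variable_id = "M320T382", mz = 320.14194,
                         rt_min = 6.37)
  res <- match_markers(eligible, lib)
  expect_equal(res$hits$compound, "Norfloxacin")
  # printed error 4.507 came from unrounded masses; 5-decimal inputs
  # recompute to 4.498
  expect_lt(abs(res$hits$mass_error_ppm - 4.507), 0.05)
  expect_equal(res$hits$delta_rt_min, -0.14)

  # a variable 6 ppm off the only candidate stays unknown
  one <- data.frame(name = "x", exact_mass = 400, rt_min = 5)
  off <- data.frame(variable_id = "v1", mz = 400 * (1 + 6e-6), rt_min = 5)
  expect_equal(nrow(match_markers(off, one)$hits), 0)
  expect_equal(match_markers(off, one)$unknowns, "v1")

  # exact agreement gives a 0 ppm / 0 min hit
  exact <- data.frame(variable_id = "v2", mz = 400, rt_min = 5)
  hit <- match_markers(exact, one)$hits
  expect_equal(hit$mass_error_ppm, 0)
  expect_equal(hit$delta_rt_min, 0)

  # RT outside the window blocks a mass match
  far <- data.frame(variable_id = "v3", mz = 400, rt_min = 5.5)
  expect_equal(nrow(match_markers(far, one)$hits), 0)

  # smaller |ppm| wins among in-tolerance candidates
  two <- data.frame(name = c("a", "b"), exact_mass = c(400.0004, 400.0012),
                    rt_min = c(5, 5))
  expect_equal(match_markers(data.frame(variable_id = "v4", mz = 400.0006,
                                        rt_min = 5), two)$hits$compound,
               "a")
  expect_error(match_markers(exact, one[0, ]), "empty")
})

test_that("screening rates reproduce the printed percentages", {
  expect_gt(screening_rate(120, 124), 96)
  expect_equal(screening_rate(120, 124), 96.8, tolerance = 0.05)
  expect_equal(screening_rate(109, 124), 87.9, tolerance = 0.05)
  expect_equal(screening_rate(0, 124), 0)
  expect_error(screening_rate(5, 0), "positive")
  # duplicate library entries collapse when counting
  expect_equal(library_size(pvd_library()), 123)
})

test_that("detection limits follow the replicate-spike EPA formula", {
  expect_equal(lod_estimate(rep(1000, 7)), 0)
  # intensities (19,20,21,20,19,21,20): sd = 0.8165, t = 3.143, x 0.5
  lod <- lod_estimate(c(19, 20, 21, 20, 19, 21, 20))
  expect_equal(lod, qt(0.99, 6) * sd(c(19, 20, 21, 20, 19, 21, 20)) * 0.5)
  expect_equal(lod, 1.28, tolerance = 0.01)
  expect_true(lod >= 0.3 && lod <= 1.5)  # inside the published LOD range
  expect_error(lod_estimate(20), "replicates")

  # linear in the replicate sd and in extract volume / sample mass
  base <- c(19, 20, 21, 20, 19, 21, 20)
  spread <- 20 + (base - 20) * 2
  expect_equal(lod_estimate(spread), 2 * lod, tolerance = 1e-9)
  expect_equal(lod_estimate(base, extract_volume = 2), 2 * lod,
               tolerance = 1e-9)
  expect_equal(lod_estimate(base, sample_mass = 4), lod / 2,
               tolerance = 1e-9)
})

test_that("a blank run yields no library hits but a spiked-in marker is caught", {
  blank_cfg <- synthetic_config(seed = 77, n_markers = 0,
                                n_background = 120, n_erratic = 10)
  blank <- generate_spiked_dataset(blank_cfg)
  n_blank <- screen_blank(blank$table, pvd_library(), seed = 77,
                          n_permutations = 20,
                          cost_grid = 2^seq(-8, 8, 4),
                          gamma_grid = 2^seq(-8, 8, 4))
  expect_equal(n_blank, 0)

  # positive control: inject one true dose-responsive marker feature
  spiked <- blank$table
  lib1 <- pvd_library()[5, ]
  conc <- suppressWarnings(as.numeric(spiked$samples$group))
  conc[is.na(conc)] <- mean(c(20, 50, 100))  # QC columns at the pooled mean
  set.seed(5)
  row <- 1000 * conc / 20 * (1 + rnorm(length(conc), 0, 0.05))
  spiked$intensity <- rbind(spiked$intensity, marker = row)
  spiked$variables <- rbind(spiked$variables,
                            data.frame(variable_id = "MINJT1",
                                       mz = lib1$exact_mass,
                                       rt_min = lib1$rt_min,
                                       is_istd = FALSE))
  spiked <- feature_table(spiked$intensity, spiked$variables,
                          spiked$samples)
  n_spiked <- screen_blank(spiked, pvd_library(), seed = 78,
                           n_permutations = 20,
                           cost_grid = 2^seq(-8, 8, 4),
                           gamma_grid = 2^seq(-8, 8, 4))
  expect_equal(n_spiked, 1)

  empty <- ft_subset(blank$table, variables = integer(0))
  expect_equal(screen_blank(empty), 0)
})
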