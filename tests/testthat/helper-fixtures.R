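# small in-code fixtures shared across test files

# tiny deterministic feature table: 2 groups would not satisfy the design,
# so use the full 3-group + QC layout at minimal size
tiny_table <- function(n_markers = 3, n_background = 4, n_erratic = 0,
                       seed = 11, cv = 0.05, ...) {
  cfg <- synthetic_config(seed = seed, n_markers = n_markers,
                          n_background = n_background,
                          n_erratic = n_erratic, intensity_cv = cv, ...)
  generate_spiked_dataset(cfg)
}

# noise-free configuration: unit recoveries, no jitter, no drift
noiseless_config <- function(seed = 5, ...) {
  synthetic_config(seed = seed, intensity_cv = 0, bg_cv = 0,
                   bg_drift_sd = 0, bg_factor_jitter = 0,
                   recovery_range_is1 = c(100, 100),
                   recovery_range_is2 = c(100, 100),
                   ppm_jitter = 0, rt_jitter = 0, ...)
}

# two-class matrix with a planted separation for OPLS/SVM tests:
# n per class, p variables, the first n_informative shifted by delta sds
separated_classes <- function(n_per_class = 18, p = 200,
                              n_informative = 20, delta = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  cls <- rep(c("A", "B"), each = n_per_class)
  x[cls == "B", seq_len(n_informative)] <-
    x[cls == "B", seq_len(n_informative)] + delta
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, y = cls)
}
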