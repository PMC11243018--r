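#' Synthetic spiked-study configuration
#'
#' Describes the simulated study design: three spiked concentration groups
#' measured in nonuplicate plus pooled-QC injections, marker features that
#' respond linearly to concentration through a per-sample pretreatment
#' recovery, concentration-independent background features, "erratic"
#' features that vary between groups without matching any library compound,
#' and two isotope-labelled internal standards. Measurement jitter is
#' applied to accurate masses (ppm) and retention times (minutes).
#'
#' @param seed integer master seed for the generator.
#' @param n_markers number of library compounds spiked as markers.
#' @param n_background number of concentration-independent matrix features.
#' @param n_erratic number of group-dependent features whose m/z matches no
#'   library entry (non-monotone or high-variance response).
#' @param group_levels theoretical spiked concentrations in ng/mL,
#'   strictly increasing.
#' @param replicates_per_group replicate samples per concentration group.
#' @param n_qc pooled-QC injections.
#' @param recovery_range_is1,recovery_range_is2 percent recovery interval
#'   for each internal standard; per-sample recoveries are drawn uniformly
#'   within the interval, independently per standard.
#' @param intensity_cv relative intensity noise fraction (multiplicative,
#'   truncated normal) of marker and erratic features.
#' @param erratic_cv_factor noise inflation applied to erratic features.
#' @param bg_cv idiosyncratic relative noise of background features.
#' @param bg_n_factors number of latent background covariance factors:
#'   matrix background in real LC-MS tables is strongly correlated (shared
#'   matrix response and batch/run-order effects), not independent per
#'   feature.
#' @param bg_drift_sd sd (log scale) of each factor's random level per
#'   acquisition block (truncated at 1.5 sd).
#' @param bg_factor_jitter within-block sd of the latent factors.
#' @param ppm_jitter accurate-mass jitter bound in ppm.
#' @param rt_jitter retention-time jitter bound in minutes.
#' @param is_nominal nominal internal-standard concentration in the final
#'   extract (ng/mL): 0.5 mL of a 100 ng/mL spike brought to 1 mL.
#' @param is_slope,is_intercept response-curve parameters of the two
#'   internal standards (area per ng/mL, area).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_markers = 124L,
                             n_background = 1289L,
                             n_erratic = 34L,
                             group_levels = c(20, 50, 100),
                             replicates_per_group = 9L,
                             n_qc = 12L,
                             recovery_range_is1 = c(72.9, 93.6),
                             recovery_range_is2 = c(72.9, 96.4),
                             intensity_cv = 0.10,
                             erratic_cv_factor = 2.5,
                             bg_cv = 0.04,
                             bg_n_factors = 10L,
                             bg_drift_sd = 0.15,
                             bg_factor_jitter = 0.02,
                             ppm_jitter = 5,
                             rt_jitter = 0.25,
                             is_nominal = 50,
                             is_slope = c(10, 12),
                             is_intercept = c(0, 0)) {
  counts <- c(n_markers, n_background, n_erratic, replicates_per_group, n_qc)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (any(group_levels <= 0) || any(diff(group_levels) <= 0))
    stop("group_levels must be positive and strictly increasing")
  for (r in list(recovery_range_is1, recovery_range_is2))
    if (length(r) != 2 || any(r <= 0) || any(r > 100) || r[1] > r[2])
      stop("recovery ranges must lie within (0, 100] with lower <= upper")
  if (intensity_cv < 0 || bg_cv < 0) stop("noise CVs must be >= 0")
  structure(list(seed = as.integer(seed), n_markers = as.integer(n_markers),
                 n_background = as.integer(n_background),
                 n_erratic = as.integer(n_erratic),
                 group_levels = group_levels,
                 replicates_per_group = as.integer(replicates_per_group),
                 n_qc = as.integer(n_qc),
                 recovery_range_is1 = recovery_range_is1,
                 recovery_range_is2 = recovery_range_is2,
                 intensity_cv = intensity_cv,
                 erratic_cv_factor = erratic_cv_factor,
                 bg_cv = bg_cv, bg_n_factors = as.integer(bg_n_factors),
                 bg_drift_sd = bg_drift_sd,
                 bg_factor_jitter = bg_factor_jitter,
                 ppm_jitter = ppm_jitter, rt_jitter = rt_jitter,
                 is_nominal = is_nominal, is_slope = is_slope,
                 is_intercept = is_intercept),
            class = "synthetic_config")
}

#' Generate a synthetic spiked feature table with ground truth
#'
#' Marker intensity for variable j in spiked sample i is
#' `base_j * C_group(i) * recovery_i/100 * (1 + eps)` with `eps` a truncated
#' normal relative error; background features have group-independent means;
#' erratic features alternate between non-monotone group patterns and
#' high-variance dose-responsive patterns, at masses matching no library
#' record. QC columns are the pooled mean of all spiked samples with noise
#' CV `min(intensity_cv, 0.05)`. Two internal-standard features carry known
#' per-sample recoveries through their response curves. Observed m/z and RT
#' are jittered within the configured ppm / minute bounds and variable ids
#' follow the `M{nominal m/z}T{RT seconds}` dialect of peak-alignment
#' software.
#'
#' @param cfg a [synthetic_config()].
#' @param library compound library data.frame (`name`, `exact_mass`,
#'   `rt_min`); defaults to the shipped screening library.
#' @return list with elements `table` (a [feature_table()]) and `truth`
#'   (marker id to compound map, background/erratic id sets, per-sample
#'   true recoveries).
#' @export
generate_spiked_dataset <- function(cfg = synthetic_config(),
                                    library = pvd_library()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_markers > nrow(library))
    stop("n_markers exceeds the library size")
  local_rng(cfg$seed)

  levels <- cfg$group_levels
  n_rep <- cfg$replicates_per_group
  n_spiked <- length(levels) * n_rep
  groups <- rep(as.character(levels), each = n_rep)
  sample_ids <- c(paste0(groups, "-", rep(seq_len(n_rep), length(levels))),
                  paste0("QC-", seq_len(cfg$n_qc)))
  conc <- rep(levels, each = n_rep)

  # per-sample pretreatment recoveries, one draw per internal standard
  r1 <- stats::runif(n_spiked, cfg$recovery_range_is1[1],
                     cfg$recovery_range_is1[2])
  r2 <- stats::runif(n_spiked, cfg$recovery_range_is2[1],
                     cfg$recovery_range_is2[2])
  r_comb <- combined_recovery(r1, r2)

  cv <- cfg$intensity_cv
  marker_idx <- if (cfg$n_markers > 0)
    sort(sample(nrow(library), cfg$n_markers)) else integer(0)
  marker_lib <- library[marker_idx, , drop = FALSE]

  blocks <- list()
  if (cfg$n_markers > 0) {
    base <- stats::rlnorm(cfg$n_markers, log(2e4), 0.5)
    m <- outer(base, conc) * rep(r_comb / 100, each = cfg$n_markers)
    blocks$marker <- m * matrix(rel_noise(length(m), cv), nrow = cfg$n_markers)
  }
  if (cfg$n_background > 0) {
    mu <- stats::rlnorm(cfg$n_background, log(1e5), 1)
    b <- matrix(mu, cfg$n_background, n_spiked)
    if (cfg$bg_n_factors > 0 &&
        (cfg$bg_drift_sd > 0 || cfg$bg_factor_jitter > 0)) {
      # correlated matrix background: latent factors with a random level
      # per acquisition block (batch effect) plus small within-block
      # jitter; block levels are truncated and loadings capped so
      # background fold changes stay below the eligibility bound
      block_idx <- rep(seq_along(levels), each = n_rep)
      block_mean <- matrix(stats::rnorm(cfg$bg_n_factors * length(levels),
                                        0, cfg$bg_drift_sd),
                           cfg$bg_n_factors, length(levels))
      block_mean <- pmin(pmax(block_mean, -1.5 * cfg$bg_drift_sd),
                         1.5 * cfg$bg_drift_sd)
      fac <- block_mean[, block_idx, drop = FALSE] +
        matrix(stats::rnorm(cfg$bg_n_factors * n_spiked, 0,
                            cfg$bg_factor_jitter),
               cfg$bg_n_factors, n_spiked)
      cluster <- sample(cfg$bg_n_factors, cfg$n_background, replace = TRUE)
      loading <- stats::runif(cfg$n_background, 0.5, 1.5)
      b <- b * exp(loading * fac[cluster, , drop = FALSE])
    }
    blocks$background <- b * matrix(rel_noise(length(b), cfg$bg_cv),
                                    nrow = cfg$n_background)
  }
  if (cfg$n_erratic > 0) {
    e_cv <- cv * cfg$erratic_cv_factor
    base <- stats::rlnorm(cfg$n_erratic, log(5e4), 0.6)
    patt <- matrix(NA_real_, cfg$n_erratic, length(levels))
    for (j in seq_len(cfg$n_erratic)) {
      if (j %% 2 == 1) {  # non-monotone group pattern
        repeat {
          p <- sample(c(1, 2.6, 0.75), length(levels),
                      replace = length(levels) > 3)
          if (is.unsorted(p) && is.unsorted(rev(p))) break
        }
        patt[j, ] <- p
      } else {            # dose-responsive but unannotatable
        patt[j, ] <- levels / levels[1]
      }
    }
    e <- base * patt[, rep(seq_along(levels), each = n_rep), drop = FALSE]
    # recovery effect only on the dose-responsive half (they mimic spikes)
    resp <- seq_len(cfg$n_erratic) %% 2 == 0
    if (any(resp))
      e[resp, ] <- e[resp, , drop = FALSE] * rep(r_comb / 100,
                                                 each = sum(resp))
    blocks$erratic <- e * matrix(rel_noise(length(e), e_cv),
                                 nrow = cfg$n_erratic)
  }

  # internal standards: response-curve area scaled by the per-IS recovery
  istd_area <- rbind(
    (cfg$is_slope[1] * cfg$is_nominal + cfg$is_intercept[1]) * r1 / 100,
    (cfg$is_slope[2] * cfg$is_nominal + cfg$is_intercept[2]) * r2 / 100)
  istd_area <- istd_area * matrix(rel_noise(length(istd_area), cv), nrow = 2)
  blocks$istd <- istd_area

  spiked <- do.call(rbind, blocks)
  qc_cv <- min(cv, 0.05)
  qc <- matrix(rowMeans(spiked), nrow(spiked), cfg$n_qc) *
    matrix(rel_noise(nrow(spiked) * cfg$n_qc, qc_cv), nrow = nrow(spiked))
  intensity <- cbind(spiked, qc)

  # true masses / retention times; background and erratic masses avoid the
  # library so only spiked markers can be annotated
  istd_meta <- data.frame(name = c("enrofloxacin-d5", "atrazine-d5"),
                          exact_mass = c(365.21092, 221.14017),
                          rt_min = c(7.01, 5.77))
  n_free <- cfg$n_background + cfg$n_erratic
  free_mass <- draw_nonmatching_masses(n_free, c(library$exact_mass,
                                                 istd_meta$exact_mass))
  true_mass <- c(marker_lib$exact_mass,
                 free_mass,
                 istd_meta$exact_mass)
  true_rt <- c(marker_lib$rt_min,
               stats::runif(n_free, 2, 12),
               istd_meta$rt_min)
  n_var <- length(true_mass)
  mz <- true_mass * (1 + stats::runif(n_var, -cfg$ppm_jitter,
                                      cfg$ppm_jitter) * 1e-6)
  rt <- true_rt + stats::runif(n_var, -cfg$rt_jitter, cfg$rt_jitter)
  ids <- uniquify_ids(make_variable_id(mz, rt))

  kind <- rep(c("marker", "background", "erratic", "istd"),
              c(cfg$n_markers, cfg$n_background, cfg$n_erratic, 2L))
  variables <- data.frame(variable_id = ids, mz = mz, rt_min = rt,
                          is_istd = kind == "istd",
                          stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids,
                        group = c(groups, rep("QC", cfg$n_qc)),
                        type = c(rep("sample", n_spiked),
                                 rep("QC", cfg$n_qc)),
                        stringsAsFactors = FALSE)
  tab <- feature_table(intensity, variables, samples)

  truth <- list(
    marker_map = data.frame(variable_id = ids[kind == "marker"],
                            compound = marker_lib$name,
                            exact_mass = marker_lib$exact_mass,
                            rt_min = marker_lib$rt_min,
                            stringsAsFactors = FALSE),
    background_ids = ids[kind == "background"],
    erratic_ids = ids[kind == "erratic"],
    istd_ids = ids[kind == "istd"],
    recoveries = data.frame(sample_id = sample_ids[seq_len(n_spiked)],
                            group = groups, r_is1 = r1, r_is2 = r2,
                            r_combined = r_comb, stringsAsFactors = FALSE))
  list(table = tab, truth = truth)
}

# uniform masses in [100, 1000] Da at least 0.02 Da away from every
# reference mass (>= 20 ppm anywhere in range)
draw_nonmatching_masses <- function(n, reference, min_gap = 0.02) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2L * (n - length(out)) + 10L, 100, 1000)
    ok <- vapply(cand, function(m) all(abs(m - reference) > min_gap),
                 logical(1))
    out <- c(out, cand[ok])
  }
  out[seq_len(n)]
}

#' Generate an internal-standard calibration curve
#'
#' Simulates (concentration, peak area) pairs on a straight response line
#' with multiplicative noise, mirroring matrix-matched standard curves at
#' 5/10/25/50/100 ng/mL.
#'
#' @param nominal_levels concentrations in ng/mL (positive).
#' @param slope response per ng/mL (> 0).
#' @param intercept response offset.
#' @param noise_cv relative noise fraction.
#' @param seed integer seed.
#' @return data.frame with columns `level` and `area`.
#' @export
generate_is_curve <- function(nominal_levels = c(5, 10, 25, 50, 100),
                              slope = 10, intercept = 0, noise_cv = 0,
                              seed = 1L) {
  if (any(nominal_levels <= 0)) stop("levels must be positive")
  if (slope <= 0) stop("slope must be positive")
  local_rng(seed)
  area <- (slope * nominal_levels + intercept) *
    rel_noise(length(nominal_levels), noise_cv)
  data.frame(level = nominal_levels, area = area)
}

#' Spiking arithmetic
#'
#' Final concentration in the reconstituted extract after spiking a working
#' solution: e.g. 20 uL of a 1 ug/mL mix brought to a 1 mL extract gives
#' 20 ng/mL.
#'
#' @param volume_ul spiked volume in microlitres.
#' @param conc_ug_ml working-solution concentration in ug/mL.
#' @param final_volume_ml reconstituted extract volume in mL.
#' @return concentration in ng/mL.
#' @export
spike_concentration <- function(volume_ul, conc_ug_ml, final_volume_ml = 1) {
  if (final_volume_ml <= 0) stop("final volume must be positive")
  volume_ul * conc_ug_ml / final_volume_ml
}
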