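#' Screening pipeline configuration
#'
#' Collects every threshold and seed of the workflow. Exactly one input
#' route must be configured: file paths (`feature_table_path` +
#' `library_path`), a `synthetic` generator block, or a feature table passed
#' directly to [run_pipeline()].
#'
#' @param feature_table_path,library_path TSV/CSV input paths (the feature
#'   table uses the [write_feature_table()] dialect).
#' @param synthetic a [synthetic_config()], or `TRUE` for the default
#'   spiked design.
#' @param seed master seed; all stage seeds (SMOTE, folds, permutations)
#'   are derived from it.
#' @param rsd_threshold percent RSD filter bound.
#' @param vip_threshold VIP cut for the candidate lists.
#' @param p_max,fc_min univariate eligibility bounds.
#' @param ppm_tol,rt_tol identification tolerances (ppm, minutes).
#' @param n_permutations label permutations per contrast.
#' @param n_orthogonal orthogonal OPLS components (or `"auto"`).
#' @param cv_folds_opls,cv_folds_tune,cv_folds_accuracy fold counts for the
#'   OPLS Q2, the (c, g) grid search, and the final accuracy estimate.
#' @param accuracy_repeats repeats of the final cross-validated accuracy.
#' @param cost_grid,gamma_grid SVM tuning grid (powers of two by default).
#' @param smote_k SMOTE neighbour count.
#' @param smote_for_svm use the SMOTE-balanced design for SVM ranking too
#'   (default TRUE, keeping the two rankings on identical data).
#' @param per_sample_calibration recovery coefficient per sample instead of
#'   per group.
#' @param scaling `"uv"`, `"pareto"` or `"none"`.
#' @param chunk_fraction SVM-RFE chunked-elimination fraction (0 = one
#'   variable per step).
#' @param p_adjust `"none"` or `"BH"` for the pairwise t-tests.
#' @param output_dir if set, every stage writes its TSV artifact here.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table_path = NULL, library_path = NULL,
                            synthetic = NULL, seed = 1L,
                            rsd_threshold = 30, vip_threshold = 1,
                            p_max = 0.05, fc_min = 2,
                            ppm_tol = 5, rt_tol = 0.25,
                            n_permutations = 200, n_orthogonal = 1,
                            cv_folds_opls = 7, cv_folds_tune = 3,
                            cv_folds_accuracy = 10, accuracy_repeats = 10,
                            cost_grid = 2^(-10:10),
                            gamma_grid = 2^(-10:10),
                            smote_k = 5, smote_for_svm = TRUE,
                            per_sample_calibration = FALSE,
                            scaling = "uv", chunk_fraction = 0,
                            p_adjust = "none", output_dir = NULL) {
  if (!is.null(feature_table_path) && !is.null(synthetic))
    stop("configure either input paths or a synthetic block, not both")
  if (any(c(rsd_threshold, vip_threshold, p_max, fc_min, ppm_tol,
            rt_tol, n_permutations) <= 0))
    stop("thresholds must be positive")
  if (isTRUE(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments; a `synthetic:` mapping is forwarded to
#'   [synthetic_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.list(vals$synthetic))
    vals$synthetic <- do.call(synthetic_config, vals$synthetic)
  do.call(pipeline_config, vals)
}

#' Run the full screening workflow
#'
#' Preprocessing (recovery calibration, RSD filter), PCA and clustering
#' diagnostics, then per contrast (low-vs-rest and high-vs-rest): SMOTE
#' balancing, OPLS-DA with permutation-test validation and VIP, RBF-SVM
#' grid search, cross-validated accuracy and SVM-RFE ranking, and the
#' VIP-constrained weight-table prefix. The two prefixes are intersected
#' into consensus candidates, confirmed by pairwise t-tests and fold
#' changes, and the eligible variables are matched against the compound
#' library; detection limits are estimated from the lowest spiked group's
#' replicate intensities of each hit. A parallel VIP-only route (no SVM)
#' is scored for comparison.
#'
#' @param config a [pipeline_config()].
#' @param table optionally, a [feature_table()] supplied directly (then no
#'   path/synthetic input may be configured).
#' @param library compound library; defaults to the configured path, the
#'   synthetic generator's library, or the shipped screening library.
#' @param truth optional ground truth (from [generate_spiked_dataset()])
#'   used to score marker recall.
#' @param strict abort when a permutation test fails its validity rules
#'   (default TRUE; `FALSE` downgrades to a warning).
#' @param quiet suppress progress messages.
#' @return A `screening_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(config = pipeline_config(synthetic = TRUE),
                         table = NULL, library = NULL, truth = NULL,
                         strict = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  # ---- input stage -------------------------------------------------------
  if (is.null(table)) {
    n_routes <- sum(!is.null(config$feature_table_path),
                    !is.null(config$synthetic))
    if (n_routes != 1)
      stop("exactly one input route (paths or synthetic block) is required")
    if (!is.null(config$synthetic)) {
      ds <- generate_spiked_dataset(config$synthetic,
                                    library %||% pvd_library())
      table <- ds$table
      truth <- truth %||% ds$truth
      library <- library %||% pvd_library()
      say("simulated %d x %d feature table (seed %d)",
          nrow(table$intensity), ncol(table$intensity),
          config$synthetic$seed)
    } else {
      table <- read_feature_table(config$feature_table_path)
      library <- library %||%
        utils::read.csv(config$library_path, stringsAsFactors = FALSE)
      say("read %d x %d feature table from %s", nrow(table$intensity),
          ncol(table$intensity), config$feature_table_path)
    }
  }
  library <- library %||% pvd_library()

  # ---- preprocessing -----------------------------------------------------
  syn <- config$synthetic
  if (any(table$variables$is_istd)) {
    slope <- if (!is.null(syn)) syn$is_slope else c(10, 12)
    icpt <- if (!is.null(syn)) syn$is_intercept else c(0, 0)
    nominal <- if (!is.null(syn)) syn$is_nominal else 50
    fit1 <- fit_is_curve(generate_is_curve(slope = slope[1],
                                           intercept = icpt[1],
                                           noise_cv = 0.02,
                                           seed = derive_seed(seed, 11)))
    fit2 <- fit_is_curve(generate_is_curve(slope = slope[2],
                                           intercept = icpt[2],
                                           noise_cv = 0.02,
                                           seed = derive_seed(seed, 12)))
    recs <- recovery_records(table, fit1, fit2, nominal)
    cal <- calibrate(table, recs, config$per_sample_calibration)
    say("calibrated: group coefficients %s",
        paste(sprintf("%s=%.3f", names(cal$kappa), cal$kappa),
              collapse = ", "))
  } else {
    cal <- table
    cal$kappa <- NULL
    say("no internal-standard features: skipping recovery calibration")
  }
  filt <- rsd_filter(cal, config$rsd_threshold)
  say("RSD filter (< %g%%): %d of %d variables kept", config$rsd_threshold,
      nrow(filt$intensity), nrow(cal$intensity))

  # ---- multivariate diagnostics -----------------------------------------
  spiked_idx <- which(filt$samples$type == "sample")
  groups <- ft_conc_groups(filt)
  xall <- scale_matrix(t(filt$intensity), config$scaling)
  pca_model <- pca(xall, n_components = min(2, length(spiked_idx) - 1))
  xsp <- scale_matrix(t(filt$intensity[, spiked_idx, drop = FALSE]),
                      config$scaling)
  hc <- hcluster(xsp, k = length(groups))
  hc_ari <- e1071::classAgreement(table(
    hc$labels, filt$samples$group[spiked_idx]))$crand
  say("diagnostics: PCA R2X = %s; HCA adjusted Rand vs groups = %.3f",
      paste(sprintf("%.2f", pca_model$r2x), collapse = "/"), hc_ari)

  # ---- contrasts ---------------------------------------------------------
  cand_vars <- !filt$variables$is_istd
  xmat <- t(filt$intensity[cand_vars, spiked_idx, drop = FALSE])
  grp <- filt$samples$group[spiked_idx]
  contrasts <- list(low = groups[1], high = groups[length(groups)])
  contrast_out <- list()
  for (ci in seq_along(contrasts)) {
    lab <- names(contrasts)[ci]
    one <- contrasts[[ci]]
    y <- ifelse(grp == one, "one", "rest")
    bal <- smote_balance(xmat, y, k = config$smote_k,
                         seed = derive_seed(seed, 20 + ci))
    xs <- scale_matrix(bal$x, config$scaling)
    model <- oplsda_fit(xs, bal$y, config$n_orthogonal,
                        config$cv_folds_opls)
    perm <- permutation_test(xs, bal$y, config$n_permutations,
                             derive_seed(seed, 30 + ci),
                             config$n_orthogonal, config$cv_folds_opls)
    say("%s-vs-rest OPLS-DA: R2Y = %.3f, Q2 = %.3f; permutation intercepts %.3f/%.3f (p = %.4f)",
        lab, model$r2y, model$q2, perm$r2_intercept, perm$q2_intercept,
        perm$p_value)
    if (!perm$valid) {
      msg <- sprintf("%s-vs-rest model failed permutation validity rules",
                     lab)
      if (strict) stop(msg) else warning(msg)
    }
    vip_ids <- model$variable_ids[model$vip > config$vip_threshold]

    svm_x <- if (config$smote_for_svm) bal$x else xmat
    svm_y <- if (config$smote_for_svm) bal$y else y
    svm_xs <- scale_matrix(svm_x, "uv")$data
    tune <- grid_search_rbf(svm_xs, svm_y, config$cost_grid,
                            config$gamma_grid, config$cv_folds_tune,
                            derive_seed(seed, 40 + ci))
    acc10 <- cv_accuracy(svm_xs, svm_y, tune$best_cost, tune$best_gamma,
                         config$cv_folds_accuracy,
                         config$accuracy_repeats,
                         derive_seed(seed, 50 + ci))
    wt <- svmrfe_rank(svm_x, svm_y, tune, config$chunk_fraction)
    pref <- retained_prefix(vip_ids, wt)
    say("%s-vs-rest SVM: best (c, g) = (%.4g, %.4g), 10-fold accuracy %.1f%%; %d VIP > %g in a %d-variable prefix (overlap %.1f%%)",
        lab, tune$best_cost, tune$best_gamma, acc10, length(vip_ids),
        config$vip_threshold, pref$prefix_length,
        pref$overlap_ratio %||% NA)
    contrast_out[[lab]] <- list(label = paste0(lab, "-vs-rest"),
                                model = model, perm = perm,
                                vip_list = vip_ids, tuning = tune,
                                cv10_accuracy = acc10, weight_table = wt,
                                prefix = pref)
  }

  # ---- consensus + univariate confirmation ------------------------------
  candidates <- consensus_candidates(contrast_out$low$prefix,
                                     contrast_out$high$prefix)
  vip_only <- intersect(contrast_out$low$vip_list,
                        contrast_out$high$vip_list)
  pvals <- pairwise_ttests(filt, adjust = config$p_adjust)
  fcs <- fold_changes(filt)
  eligible <- confirm_eligible(candidates, pvals, fcs, config$p_max,
                               config$fc_min)
  eligible_vip <- confirm_eligible(vip_only, pvals, fcs, config$p_max,
                                   config$fc_min)
  say("consensus: %d candidates (weight route), %d (VIP-only); eligible: %d / %d",
      length(candidates), length(vip_only), sum(eligible$eligible),
      sum(eligible_vip$eligible))

  # ---- identification ----------------------------------------------------
  lib_n <- library_size(library)
  elig_meta <- function(es) {
    ids <- es$variable_id[es$eligible]
    vi <- match(ids, filt$variables$variable_id)
    data.frame(variable_id = ids, mz = filt$variables$mz[vi],
               rt_min = filt$variables$rt_min[vi],
               stringsAsFactors = FALSE)
  }
  matched <- match_markers(elig_meta(eligible), library, config$ppm_tol,
                           config$rt_tol)
  matched_vip <- match_markers(elig_meta(eligible_vip), library,
                               config$ppm_tol, config$rt_tol)
  rate_weight <- screening_rate(matched$hits, lib_n)
  rate_vip <- screening_rate(matched_vip$hits, lib_n)

  hits <- matched$hits
  if (nrow(hits)) {
    low_cols <- ft_group_cols(filt, groups[1])
    hits$lod_ug_kg <- vapply(hits$variable_id, function(v) {
      vi <- match(v, filt$variables$variable_id)
      lod_estimate(filt$intensity[vi, low_cols],
                   spike_level = as.numeric(groups[1]))
    }, numeric(1))
  }
  say("identified %d distinct compounds of %d (screening rate %.1f%%; VIP-only %.1f%%); %d unknowns",
      nrow(unique(hits[c("compound", "reference_mass")])), lib_n,
      rate_weight, rate_vip, length(matched$unknowns))

  report <- structure(list(
    table = filt, pca = pca_model, hcluster = hc, hc_ari = hc_ari,
    contrasts = contrast_out, candidates = candidates,
    vip_only_candidates = vip_only, pvalues = pvals, fold_changes = fcs,
    eligible = eligible, eligible_vip = eligible_vip,
    hits = hits, unknowns = matched$unknowns,
    screening_rate_weight = rate_weight, screening_rate_vip = rate_vip,
    library_n = lib_n, config = config), class = "screening_report")

  if (!is.null(truth)) {
    marker_ids <- truth$marker_map$variable_id
    report$recall_weight <-
      100 * sum(marker_ids %in% hits$variable_id) / length(marker_ids)
    report$recall_vip <-
      100 * sum(marker_ids %in% matched_vip$hits$variable_id) /
      length(marker_ids)
    say("ground truth: marker recall %.1f%% (weight route), %.1f%% (VIP-only)",
        report$recall_weight, report$recall_vip)
  }
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening report\n")
  cat(sprintf("  variables after filtering: %d\n", nrow(x$table$intensity)))
  for (co in x$contrasts)
    cat(sprintf("  %s: R2Y %.2f, Q2 %.2f, prefix %d (overlap %.1f%%), 10-fold acc %.1f%%\n",
                co$label, co$model$r2y, co$model$q2,
                co$prefix$prefix_length, co$prefix$overlap_ratio,
                co$cv10_accuracy))
  cat(sprintf("  candidates %d -> eligible %d -> hits %d (rate %.1f%%; VIP-only %.1f%%)\n",
              length(x$candidates), sum(x$eligible$eligible), nrow(x$hits),
              x$screening_rate_weight, x$screening_rate_vip))
  invisible(x)
}

#' Write the stage artifacts of a screening report as TSV files
#'
#' @param report a `screening_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(report$table$filter_report, "filter_report.tsv")
  w(data.frame(sample_id = rownames(report$pca$scores), report$pca$scores),
    "pca_scores.tsv")
  for (lab in names(report$contrasts)) {
    co <- report$contrasts[[lab]]
    w(data.frame(variable_id = co$model$variable_ids, vip = co$model$vip,
                 p1 = co$model$p1, pcorr1 = co$model$pcorr1),
      sprintf("opls_%s.tsv", lab))
    w(co$perm$iterations, sprintf("permutations_%s.tsv", lab))
    w(as.data.frame(co$weight_table), sprintf("weight_table_%s.tsv", lab))
  }
  w(as.data.frame(report$eligible), "eligibility.tsv")
  w(report$hits, "marker_hits.tsv")
  summary <- data.frame(
    metric = c("screening_rate_weight", "screening_rate_vip",
               "library_size", "hc_adjusted_rand"),
    value = c(report$screening_rate_weight, report$screening_rate_vip,
              report$library_n, report$hc_ari))
  if (!is.null(report$recall_weight))
    summary <- rbind(summary,
                     data.frame(metric = c("recall_weight", "recall_vip"),
                                value = c(report$recall_weight,
                                          report$recall_vip)))
  w(summary, "summary.tsv")
  invisible(dir)
}
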