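#' Fit an internal-standard response curve
#'
#' Ordinary least-squares line through (concentration, area) calibration
#' points from matrix-matched standards.
#'
#' @param curve data.frame with columns `level` (ng/mL) and `area`.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_is_curve <- function(curve) {
  if (nrow(curve) < 2 || length(unique(curve$level)) < 2)
    stop("need at least 2 distinct calibration levels")
  fit <- stats::lm(area ~ level, data = curve)
  tss <- sum((curve$area - mean(curve$area))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Internal-standard recovery from a measured peak area
#'
#' Back-calculates the measured concentration through the response curve and
#' expresses it as a percentage of the nominal spiked concentration.
#'
#' @param area measured peak area(s).
#' @param fit line fit from [fit_is_curve()] (elements `slope`, `intercept`).
#' @param nominal nominal concentration in ng/mL (> 0).
#' @return recovery in percent.
#' @export
is_recovery <- function(area, fit, nominal) {
  if (nominal <= 0) stop("nominal concentration must be positive")
  if (fit$slope == 0) stop("zero slope: curve cannot be inverted")
  measured <- (area - fit$intercept) / fit$slope
  100 * measured / nominal
}

#' Combined recovery of two internal standards
#'
#' Harmonic mean of the two percent recoveries,
#' `2 / (1/r1 + 1/r2) * 100%` on the percent scale. Symmetric in its
#' arguments and never above their arithmetic mean.
#'
#' @param r1,r2 percent recoveries (> 0); vectorised.
#' @return combined percent recovery.
#' @export
combined_recovery <- function(r1, r2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("recoveries must be positive")
  2 / (1 / r1 + 1 / r2)
}

#' Per-sample recovery records from internal-standard features
#'
#' Reads the two internal-standard rows of a feature table (in row order:
#' first and second flagged `is_istd`), back-calculates each standard's
#' percent recovery through its response curve, and combines them.
#'
#' @param table a [feature_table()] carrying two `is_istd` variables.
#' @param fit_is1,fit_is2 line fits from [fit_is_curve()].
#' @param nominal nominal internal-standard concentration (ng/mL).
#' @return data.frame with `sample_id`, `group`, `r_is1`, `r_is2`,
#'   `r_combined` for every non-QC sample.
#' @export
recovery_records <- function(table, fit_is1, fit_is2, nominal = 50) {
  is_rows <- which(table$variables$is_istd)
  if (length(is_rows) != 2)
    stop("feature table must carry exactly two internal-standard variables")
  keep <- table$samples$type == "sample"
  a1 <- table$intensity[is_rows[1], keep]
  a2 <- table$intensity[is_rows[2], keep]
  data.frame(sample_id = table$samples$sample_id[keep],
             group = table$samples$group[keep],
             r_is1 = is_recovery(a1, fit_is1, nominal),
             r_is2 = is_recovery(a2, fit_is2, nominal),
             r_combined = combined_recovery(is_recovery(a1, fit_is1, nominal),
                                            is_recovery(a2, fit_is2, nominal)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recovery calibration of a feature table
#'
#' Per concentration group, a calibration coefficient
#' `kappa = 100 / mean(combined recovery)` rescales every intensity of that
#' group's samples so the group-mean recovery becomes 100%. QC columns are
#' rescaled by the mean of the group coefficients. With `per_sample = TRUE`
#' each sample is instead rescaled by its own `100 / r_combined`.
#'
#' @param table a [feature_table()].
#' @param recoveries data.frame from [recovery_records()] (columns
#'   `sample_id`, `group`, `r_combined`); every non-QC sample must appear.
#' @param per_sample logical; per-sample instead of per-group coefficients.
#' @return A `calibrated_table`: the feature table with a `kappa` named
#'   vector (one coefficient per group plus `"QC"`) and the recovery records
#'   attached.
#' @export
calibrate <- function(table, recoveries, per_sample = FALSE) {
  non_qc <- table$samples$sample_id[table$samples$type == "sample"]
  missing <- setdiff(non_qc, recoveries$sample_id)
  if (length(missing))
    stop("missing recovery record for sample(s): ",
         paste(missing, collapse = ", "))
  groups <- ft_conc_groups(table)
  kappa <- vapply(groups, function(g) {
    100 / mean(recoveries$r_combined[recoveries$group == g])
  }, numeric(1))
  out <- table
  if (per_sample) {
    k_sample <- 100 / recoveries$r_combined[
      match(non_qc, recoveries$sample_id)]
    idx <- match(non_qc, table$samples$sample_id)
    out$intensity[, idx] <- sweep(out$intensity[, idx, drop = FALSE], 2,
                                  k_sample, `*`)
  } else {
    for (g in groups) {
      idx <- ft_group_cols(table, g)
      out$intensity[, idx] <- out$intensity[, idx, drop = FALSE] * kappa[[g]]
    }
  }
  qc_idx <- which(table$samples$type == "QC")
  if (length(qc_idx))
    out$intensity[, qc_idx] <- out$intensity[, qc_idx, drop = FALSE] *
      mean(kappa)
  out$kappa <- c(kappa, QC = mean(kappa))
  out$recoveries <- recoveries
  class(out) <- c("calibrated_table", class(table))
  out
}

#' Reproducibility (RSD) variable filter
#'
#' Keeps variables whose relative standard deviation of peak intensity is
#' strictly below the threshold within the QC injections and within every
#' concentration group. Internal-standard variables are always retained
#' (they are excluded from candidate ranking downstream, not from the
#' table). The per-group RSDs of every variable are attached as
#' `filter_report`.
#'
#' @param table a (calibrated) [feature_table()].
#' @param threshold percent RSD bound (default 30; strict `<`).
#' @return The filtered table, with `filter_report` attached.
#' @export
rsd_filter <- function(table, threshold = 30) {
  grp <- c(ft_conc_groups(table),
           if (any(table$samples$type == "QC")) "QC")
  rsd <- sapply(grp, function(g) {
    idx <- if (g == "QC") which(table$samples$type == "QC")
           else ft_group_cols(table, g)
    if (length(idx) < 2)
      stop("group '", g, "' has fewer than 2 columns")
    apply(table$intensity[, idx, drop = FALSE], 1, rsd_pct)
  })
  rsd <- matrix(rsd, nrow = nrow(table$intensity),
                dimnames = list(NULL, paste0("rsd_", grp)))
  keep <- apply(rsd < threshold, 1, all) | table$variables$is_istd
  report <- cbind(
    data.frame(variable_id = table$variables$variable_id,
               stringsAsFactors = FALSE),
    as.data.frame(rsd), kept = keep)
  out <- ft_subset(table, variables = which(keep))
  out$kappa <- table$kappa
  out$recoveries <- table$recoveries
  out$filter_report <- report
  class(out) <- unique(c("calibrated_table", class(out)))
  out
}
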