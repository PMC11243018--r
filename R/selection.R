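#' Combine a VIP list with an SVM-RFE weight table
#'
#' The retained candidate set of a contrast is the smallest w2-descending
#' prefix of the weight table that still contains every VIP > 1 variable:
#' variables with VIP < 1 that rank above the worst VIP > 1 member are kept
#' to avoid losing valid variables during VIP computation.
#'
#' @param vip_list character vector of variable ids with VIP > 1.
#' @param weight_table a `weight_table` from [svmrfe_rank()] (w2-descending
#'   order).
#' @return A `contrast_result`: `prefix` (character vector, contiguous head
#'   of the weight order), `vip_list`, `prefix_length`, `overlap_ratio`
#'   (percent, 1 decimal; NA for an empty prefix).
#' @export
retained_prefix <- function(vip_list, weight_table) {
  wt_ids <- weight_table$variable_id
  missing <- setdiff(vip_list, wt_ids)
  if (length(missing))
    stop("VIP variable(s) absent from the weight table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- if (length(vip_list) == 0) 0L else max(match(vip_list, wt_ids))
  prefix <- wt_ids[seq_len(len)]
  structure(list(prefix = prefix,
                 vip_list = vip_list,
                 prefix_length = len,
                 overlap_ratio = if (len > 0)
                   overlap_ratio(vip_list, prefix) else NA_real_),
            class = "contrast_result")
}

#' Overlap ratio between a VIP list and a weight-table prefix
#'
#' `100 * |vip_list intersect prefix| / |prefix|`, rounded to one decimal:
#' the agreement between the VIP and weight ranking routes for one
#' contrast.
#'
#' @param vip_list,prefix character vectors of variable ids.
#' @return percent, one decimal.
#' @export
overlap_ratio <- function(vip_list, prefix) {
  if (length(prefix) == 0) stop("empty prefix")
  round(100 * length(intersect(vip_list, prefix)) / length(prefix), 1)
}

#' Consensus candidates of the two one-vs-rest contrasts
#'
#' @param contrast_low,contrast_high `contrast_result`s (low-vs-rest and
#'   high-vs-rest).
#' @return character vector: intersection of the two retained prefixes.
#' @export
consensus_candidates <- function(contrast_low, contrast_high) {
  intersect(contrast_low$prefix, contrast_high$prefix)
}

#' Pairwise Welch t-tests across concentration groups
#'
#' Two-sided two-sample Welch tests of calibrated peak intensity for each
#' of the three group pairs (low-mid, low-high, mid-high). p-values are
#' raw (no multiplicity adjustment); `adjust = "BH"` applies
#' Benjamini-Hochberg within each pair. A variable with zero variance in
#' both groups of a pair gets p = 1 and a warning flag.
#'
#' @param table a calibrated [feature_table()].
#' @param variables variable ids to test (default: all non-internal-standard
#'   variables).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `variable_id`, one p-value column per group pair
#'   (e.g. `p_20vs50`), and `degenerate` flag.
#' @export
pairwise_ttests <- function(table, variables = NULL, adjust = "none") {
  groups <- ft_conc_groups(table)
  if (length(groups) < 2) stop("need at least two concentration groups")
  if (is.null(variables))
    variables <- table$variables$variable_id[!table$variables$is_istd]
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  idx_of <- lapply(groups, function(g) ft_group_cols(table, g))
  names(idx_of) <- groups
  for (g in groups)
    if (length(idx_of[[g]]) < 2)
      stop("group '", g, "' has fewer than 2 samples")
  vi <- match(variables, table$variables$variable_id)
  out <- data.frame(variable_id = variables, stringsAsFactors = FALSE)
  degenerate <- rep(FALSE, length(variables))
  for (pr in pairs) {
    a <- table$intensity[vi, idx_of[[pr[1]]], drop = FALSE]
    b <- table$intensity[vi, idx_of[[pr[2]]], drop = FALSE]
    p <- vapply(seq_along(variables), function(j) {
      if (stats::sd(a[j, ]) == 0 && stats::sd(b[j, ]) == 0) {
        degenerate[j] <<- TRUE
        return(1)
      }
      stats::t.test(a[j, ], b[j, ], var.equal = FALSE)$p.value
    }, numeric(1))
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    out[[paste0("p_", pr[1], "vs", pr[2])]] <- p
  }
  out$degenerate <- degenerate
  if (any(degenerate))
    warning(sum(degenerate), " variable(s) had zero variance in a pair; ",
            "p set to 1")
  out
}

#' Fold changes of concentration between group means
#'
#' `FC = mean(higher group) / mean(lowest group)` of calibrated intensity,
#' one column per non-baseline group (e.g. `FC_50vs20`, `FC_100vs20`).
#'
#' @param table a calibrated [feature_table()].
#' @param variables variable ids (default: all non-internal-standard).
#' @return data.frame with `variable_id` and one FC column per contrast.
#' @export
fold_changes <- function(table, variables = NULL) {
  groups <- ft_conc_groups(table)
  if (is.null(variables))
    variables <- table$variables$variable_id[!table$variables$is_istd]
  vi <- match(variables, table$variables$variable_id)
  base <- groups[1]
  mu_base <- rowMeans(table$intensity[vi, ft_group_cols(table, base),
                                      drop = FALSE])
  if (any(mu_base <= 0)) stop("non-positive mean in the baseline group")
  out <- data.frame(variable_id = variables, stringsAsFactors = FALSE)
  for (g in groups[-1]) {
    mu <- rowMeans(table$intensity[vi, ft_group_cols(table, g),
                                   drop = FALSE])
    out[[paste0("FC_", g, "vs", base)]] <- mu / mu_base
  }
  out
}

#' Univariate confirmation of candidate variables
#'
#' A candidate is eligible when all pairwise p-values are below `p_max` and
#' all fold changes exceed `fc_min`. Failing candidates are retained with
#' the reasons they failed.
#'
#' @param candidates character vector of variable ids.
#' @param pvals data.frame from [pairwise_ttests()].
#' @param fcs data.frame from [fold_changes()].
#' @param p_max significance bound (default 0.05).
#' @param fc_min fold-change bound (default 2).
#' @return An `eligible_set` data.frame: candidates with their statistics,
#'   logical `eligible`, and `reason` for exclusion.
#' @export
confirm_eligible <- function(candidates, pvals, fcs, p_max = 0.05,
                             fc_min = 2) {
  pv <- pvals[match(candidates, pvals$variable_id), , drop = FALSE]
  fc <- fcs[match(candidates, fcs$variable_id), , drop = FALSE]
  if (anyNA(pv$variable_id) || anyNA(fc$variable_id))
    stop("statistics missing for some candidates")
  p_cols <- grep("^p_", names(pv), value = TRUE)
  fc_cols <- grep("^FC_", names(fc), value = TRUE)
  p_ok <- apply(as.matrix(pv[p_cols]) < p_max, 1, all)
  fc_ok <- apply(as.matrix(fc[fc_cols]) > fc_min, 1, all)
  reason <- character(length(candidates))
  reason[!p_ok] <- "p-value"
  reason[!fc_ok] <- ifelse(reason[!fc_ok] == "", "fold-change",
                           "p-value + fold-change")
  out <- cbind(data.frame(variable_id = candidates,
                          stringsAsFactors = FALSE),
               pv[p_cols], fc[fc_cols],
               eligible = p_ok & fc_ok, reason = reason)
  rownames(out) <- NULL
  class(out) <- c("eligible_set", class(out))
  out
}
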