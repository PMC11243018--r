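#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary contrast, in regression form: class labels are encoded -1/+1 and
#' centered, `n_orthogonal` label-orthogonal components are removed from X
#' by OSC-style deflation, and a single predictive component is fitted on
#' the deflated matrix. R2Y is the fraction of label variance explained on
#' the training data; Q2 comes from k-fold cross-validation with
#' deterministic interleaved ("venetian blind") folds, refitting the column
#' scaling inside each fold. Per-variable VIP scores (mean square one) and
#' S-plot statistics (covariance and correlation of each scaled variable
#' with the predictive score) are populated on the fitted model.
#'
#' @param x a [scale_matrix()] result (samples x variables; the raw matrix
#'   and scaling mode it carries are used to rescale training folds), or a
#'   plain pre-scaled matrix.
#' @param y two-class labels (factor, character or numeric); the
#'   lexicographically first class is encoded -1.
#' @param n_orthogonal number of orthogonal components (>= 0), or `"auto"`
#'   to keep adding components while each removes at least 1% of the X
#'   variance (up to 5).
#' @param cv_folds folds for the Q2 cross-validation (default 7).
#' @return An `opls_model` with predictive scores `t`, loadings `p`,
#'   weights `w`, regression coefficient `c_coef`, orthogonal component
#'   list, `r2y`, `q2`, `vip`, and S-plot columns `p1` / `pcorr1`.
#' @export
oplsda_fit <- function(x, y, n_orthogonal = 1, cv_folds = 7) {
  enc <- encode_labels(y)
  sm <- as_scaled(x)
  X <- sm$data
  if (nrow(X) != length(enc$y)) stop("x and y sizes disagree")
  auto <- identical(n_orthogonal, "auto")
  if (!auto && n_orthogonal < 0) stop("n_orthogonal must be >= 0")

  yc <- enc$y - mean(enc$y)
  core <- opls_core(X, yc, if (auto) 5L else n_orthogonal, auto = auto)
  yhat <- core$t * core$c_coef
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)

  q2 <- opls_q2(sm, enc$y, length(core$ortho), cv_folds)

  p_vars <- ncol(X)
  vip <- sqrt(p_vars) * abs(core$w) / sqrt(sum(core$w^2))
  p1 <- as.numeric(stats::cov(core$t, X))
  pcorr1 <- as.numeric(stats::cor(core$t, X))
  pcorr1[is.na(pcorr1)] <- 0  # constant columns

  structure(list(t = core$t, p = core$p, w = core$w, c_coef = core$c_coef,
                 ortho = core$ortho, r2y = r2y, q2 = q2, vip = vip,
                 p1 = p1, pcorr1 = pcorr1, y_enc = enc$y,
                 levels = enc$levels, scaling = sm,
                 n_orthogonal = length(core$ortho), cv_folds = cv_folds,
                 variable_ids = colnames(X)),
            class = "opls_model")
}

# NIPALS-style OPLS core on a scaled matrix and centered response
opls_core <- function(X, yc, n_ortho, auto = FALSE) {
  w <- drop(crossprod(X, yc)) / sum(yc^2)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("response is orthogonal to every variable")
  w <- w / nw
  ssx_total <- sum(X^2)
  ortho <- list()
  Xd <- X
  for (a in seq_len(n_ortho)) {
    t_pred <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    w_o <- p - sum(w * p) * w
    n_o <- sqrt(sum(w_o^2))
    if (n_o < 1e-12) break
    w_o <- w_o / n_o
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    removed <- sum(t_o^2) * sum(p_o^2) / ssx_total
    if (auto && a > 1 && removed < 0.01) break
    Xd <- Xd - tcrossprod(t_o, p_o)
    ortho[[a]] <- list(w = w_o, t = t_o, p = p_o, r2x_removed = removed)
  }
  t_pred <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  c_coef <- sum(yc * t_pred) / sum(t_pred^2)
  # sign convention: predictive score correlates positively with the label
  if (c_coef < 0) {
    w <- -w; t_pred <- -t_pred; p <- -p; c_coef <- -c_coef
  }
  list(w = w, t = t_pred, p = p, c_coef = c_coef, ortho = ortho)
}

# interleaved k-fold cross-validated Q2 on the +-1 response
opls_q2 <- function(sm, y_enc, n_ortho, cv_folds) {
  n <- length(y_enc)
  cv_folds <- min(cv_folds, n)
  fold <- ((seq_len(n) - 1L) %% cv_folds) + 1L
  press <- 0
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    sm_tr <- scale_matrix(sm$raw[tr, , drop = FALSE], sm$mode)
    y_tr <- y_enc[tr]
    core <- opls_core(sm_tr$data, y_tr - mean(y_tr), n_ortho)
    Xte <- apply_scaling(sm_tr, sm$raw[!tr, , drop = FALSE])
    for (oc in core$ortho)
      Xte <- Xte - tcrossprod(drop(Xte %*% oc$w), oc$p)
    yhat <- drop(Xte %*% core$w) * core$c_coef + mean(y_tr)
    press <- press + sum((y_enc[!tr] - yhat)^2)
  }
  1 - press / sum((y_enc - mean(y_enc))^2)
}

as_scaled <- function(x) {
  if (inherits(x, "scaled_matrix")) return(x)
  x <- as.matrix(x)
  # treat a plain matrix as already transformed; identity scaling
  structure(list(data = x, raw = x, center = rep(0, ncol(x)),
                 scale = rep(1, ncol(x)), mode = "none"),
            class = "scaled_matrix")
}

encode_labels <- function(y) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("y must contain exactly 2 classes")
  list(y = ifelse(as.character(y) == lev[1], -1, 1), levels = lev)
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a)`. With one
#' predictive component this reduces to `sqrt(p) |w_j| / ||w||`, and the
#' mean of VIP^2 over variables is exactly 1.
#'
#' @param model a fitted [oplsda_fit()] model.
#' @return numeric vector of per-variable VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("not a fitted OPLS-DA model")
  model$vip
}

#' S-plot statistics
#'
#' @param model a fitted [oplsda_fit()] model.
#' @return data.frame with `variable_id`, `p1` (covariance of the scaled
#'   variable with the predictive score) and `pcorr1` (correlation).
#' @export
splot <- function(model) {
  if (!inherits(model, "opls_model")) stop("not a fitted OPLS-DA model")
  data.frame(variable_id = model$variable_ids %||%
               paste0("V", seq_along(model$p1)),
             p1 = model$p1, pcorr1 = model$pcorr1,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: 1 predictive + %d orthogonal component(s), %d variables\n",
    x$n_orthogonal, length(x$w)))
  cat(sprintf("  R2Y = %.3f   Q2 = %.3f  (%d-fold CV)\n",
              x$r2y, x$q2, x$cv_folds))
  invisible(x)
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the model `n_iter` times under randomly permuted class labels,
#' recording for each iteration the absolute correlation between permuted
#' and original labels and the permuted R2Y and Q2Y. Straight lines are
#' fitted through each point set together with the unpermuted point (at
#' correlation 1); their intercepts estimate the background R2Y/Q2Y a
#' random labelling attains. The empirical p-value of Q2 is
#' `(1 + #[Q2_perm >= Q2_orig]) / (n_iter + 1)`. The model is flagged valid
#' when the R2Y-intercept is <= 0.4, the Q2Y-intercept is <= 0.05 and
#' p < 0.05; an R2Y-intercept above 0.3 additionally raises a caution flag.
#'
#' Permuted refits use the PLS-equivalent model (`perm_orthogonal = 0`
#' orthogonal components) by default, the convention of chemometrics
#' software for OPLS permutation plots: refitting the orthogonal filter
#' under permuted labels would remove exactly the label-orthogonal variance
#' for *any* labelling and so inflate permuted R2Y by construction.
#'
#' @param x matrix or [scale_matrix()] result.
#' @param y two-class labels.
#' @param n_iter permutation count (>= 10; default 200).
#' @param seed integer seed driving the permutations.
#' @param n_orthogonal,cv_folds passed to [oplsda_fit()] for the reported
#'   reference model.
#' @param perm_orthogonal orthogonal components of the permuted refits and
#'   of the unpermuted anchor point (default 0, the PLS-equivalent model).
#' @return A `perm_result`: per-iteration table, `r2_intercept`,
#'   `q2_intercept`, `p_value`, `valid`, `r2_caution`, the reference-model
#'   `r2y` / `q2`, and the anchor values `r2y_anchor` / `q2_anchor`.
#' @export
permutation_test <- function(x, y, n_iter = 200, seed = 1L,
                             n_orthogonal = 1, cv_folds = 7,
                             perm_orthogonal = 0) {
  if (n_iter < 10) stop("n_iter must be >= 10")
  model <- oplsda_fit(x, y, n_orthogonal, cv_folds)
  anchor <- if (identical(perm_orthogonal, n_orthogonal)) model
            else oplsda_fit(x, y, perm_orthogonal, cv_folds)
  local_rng(seed)
  y_enc <- model$y_enc
  res <- matrix(NA_real_, n_iter, 3,
                dimnames = list(NULL, c("correlation", "r2y", "q2")))
  for (i in seq_len(n_iter)) {
    y_perm <- sample(y_enc)
    m <- oplsda_fit(x, y_perm, perm_orthogonal, cv_folds)
    res[i, ] <- c(abs(stats::cor(y_perm, y_enc)), m$r2y, m$q2)
  }
  pts_x <- c(res[, "correlation"], 1)
  r2_line <- stats::lm(c(res[, "r2y"], anchor$r2y) ~ pts_x)
  q2_line <- stats::lm(c(res[, "q2"], anchor$q2) ~ pts_x)
  r2_int <- unname(stats::coef(r2_line)[1])
  q2_int <- unname(stats::coef(q2_line)[1])
  p_val <- (1 + sum(res[, "q2"] >= anchor$q2)) / (n_iter + 1)
  structure(list(iterations = as.data.frame(res),
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 p_value = p_val,
                 valid = r2_int <= 0.4 && q2_int <= 0.05 && p_val < 0.05,
                 r2_caution = r2_int > 0.3,
                 r2y = model$r2y, q2 = model$q2,
                 r2y_anchor = anchor$r2y, q2_anchor = anchor$q2,
                 n_iter = n_iter),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test (%d iterations)\n", x$n_iter))
  cat(sprintf("  model R2Y = %.3f, Q2 = %.3f\n", x$r2y, x$q2))
  cat(sprintf("  R2Y-intercept = %.3f, Q2Y-intercept = %.3f, p = %.4f\n",
              x$r2_intercept, x$q2_intercept, x$p_value))
  cat(sprintf("  valid: %s%s\n", x$valid,
              if (x$r2_caution) " (R2Y-intercept above 0.3)" else ""))
  invisible(x)
}
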