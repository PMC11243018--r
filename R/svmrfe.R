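#' SVM-RFE variable ranking under the RBF kernel
#'
#' Recursive feature elimination with the kernel-space ranking criterion:
#' at every step an RBF SVM is trained on the surviving variables and each
#' variable i is scored by the margin change
#' `DJ(i) = 1/2 a' K a - 1/2 a' K(-i) a`, where `a` holds the signed
#' support-vector coefficients, `K` is the RBF kernel matrix over the
#' support vectors and `K(-i)` the same matrix with variable i removed
#' (multipliers held fixed, the standard RFE approximation). The
#' minimum-score variable is eliminated; its score at elimination time is
#' reported as the weight-squared value w2 and a sign taken from the
#' univariate class-mean difference gives the signed weight
#' `w = sign * sqrt(w2)`. The table is returned sorted by w2 descending.
#'
#' Variables are unit-variance scaled internally before fitting. One
#' variable is removed per step; for larger tables `chunk_fraction` drops
#' the worst fraction of the survivors per step instead.
#'
#' @param x numeric matrix, samples in rows.
#' @param y two-class labels.
#' @param tuning an `svm_tuning` from [grid_search_rbf()], or a list with
#'   `best_cost` and `best_gamma`.
#' @param chunk_fraction drop this fraction of surviving variables per step
#'   (0 = one at a time).
#' @return A `weight_table` data.frame: `variable_id`, `w`, `w2`,
#'   `elimination_rank` (1 = eliminated last, i.e. most important), sorted
#'   by `w2` descending, with the tuning attached as an attribute.
#' @export
svmrfe_rank <- function(x, y, tuning, chunk_fraction = 0) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("need at least one variable")
  ids <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- ids
  enc <- encode_labels(y)
  if (nrow(unique(x)) < 2) stop("degenerate kernel: all samples identical")
  cost <- tuning$best_cost
  gamma <- tuning$best_gamma

  xs <- scale_matrix(x, "uv")$data
  sign_w <- sign(colMeans(xs[enc$y == 1, , drop = FALSE]) -
                 colMeans(xs[enc$y == -1, , drop = FALSE]))

  surviving <- seq_len(ncol(xs))
  n_var <- ncol(xs)
  w2 <- numeric(n_var)
  elim_order <- integer(0)  # first entry = first eliminated
  yf <- factor(enc$y)

  while (length(surviving) > 0) {
    if (length(surviving) == 1) {
      # last survivor: score it against the empty model (its DJ is the
      # full margin term)
      dj <- rfe_scores(xs[, surviving, drop = FALSE], yf, cost, gamma)
      w2[surviving] <- max(dj, 0)
      elim_order <- c(elim_order, surviving)
      break
    }
    dj <- rfe_scores(xs[, surviving, drop = FALSE], yf, cost, gamma)
    n_drop <- if (chunk_fraction > 0)
      max(1L, floor(chunk_fraction * length(surviving))) else 1L
    drop_local <- order(dj)[seq_len(n_drop)]
    w2[surviving[drop_local]] <- pmax(dj[drop_local], 0)
    elim_order <- c(elim_order, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }

  elimination_rank <- integer(n_var)
  elimination_rank[elim_order] <- rev(seq_len(n_var))
  tab <- data.frame(variable_id = ids,
                    w = sign_w * sqrt(w2),
                    w2 = w2,
                    elimination_rank = elimination_rank,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$w2, tab$elimination_rank), ]
  rownames(tab) <- NULL
  attr(tab, "tuning") <- tuning
  class(tab) <- c("weight_table", class(tab))
  tab
}

# DJ ranking scores for every variable of the current survivor matrix
rfe_scores <- function(xs, yf, cost, gamma) {
  m <- e1071::svm(xs, yf, type = "C-classification", kernel = "radial",
                  cost = cost, gamma = gamma, scale = FALSE)
  sv <- as.matrix(m$SV)
  a <- as.numeric(m$coefs)  # y_i * alpha_i
  nsv <- nrow(sv)
  if (nsv < 1) stop("SVM fit produced no support vectors")
  # squared distances over SVs, and per-variable contributions
  d2 <- as.matrix(stats::dist(sv))^2
  K <- exp(-gamma * d2)
  B <- tcrossprod(a) * K          # a_k a_l K_kl
  full <- 0.5 * sum(B)
  # K(-i) = K * exp(gamma * d2_i): removing a variable shrinks distances.
  # Vectorised over variables: E[(k,l), i] = (sv[k,i] - sv[l,i])^2
  E <- (sv[rep(seq_len(nsv), times = nsv), , drop = FALSE] -
        sv[rep(seq_len(nsv), each = nsv), , drop = FALSE])^2
  full - 0.5 * colSums(as.vector(B) * exp(gamma * E))
}
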