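#' SMOTE class balancing
#'
#' Synthetic minority over-sampling: grows the minority class to the
#' majority size by interpolating between each randomly chosen minority
#' sample and one of its `k` nearest minority neighbours (Euclidean
#' distance), `x_new = x + u * (x_nb - x)` with `u ~ Uniform(0, 1)`. Every
#' synthetic row is therefore a convex combination of exactly two original
#' minority rows. Applied in the calibrated intensity space, before any
#' scaling, so synthetic samples do not leak scaling statistics.
#'
#' @param x numeric matrix, samples in rows.
#' @param y two-class labels, one per row.
#' @param k number of nearest neighbours (default 5; must be < minority
#'   size).
#' @param seed integer seed.
#' @return A `balanced_design`: `x` (augmented matrix), `y`, `provenance`
#'   (`"original"` / `"synthetic"` per row), `k`, `seed`.
#' @export
smote_balance <- function(x, y, k = 5, seed = 1L) {
  x <- as.matrix(x)
  enc <- encode_labels(y)
  counts <- table(factor(enc$y, levels = c(-1, 1)))
  out <- list(x = x, y = y, provenance = rep("original", nrow(x)),
              k = k, seed = as.integer(seed))
  class(out) <- "balanced_design"
  if (counts[1] == counts[2]) return(out)
  minority_code <- if (counts[1] < counts[2]) -1 else 1
  min_idx <- which(enc$y == minority_code)
  n_min <- length(min_idx)
  if (n_min < 2) stop("minority class needs at least 2 samples")
  if (k >= n_min) stop("k must be smaller than the minority class size")
  n_syn <- max(counts) - n_min

  local_rng(seed)
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))

  syn <- matrix(NA_real_, n_syn, ncol(x))
  for (s in seq_len(n_syn)) {
    i <- sample.int(n_min, 1)
    j <- nn[i, sample.int(k, 1)]
    u <- stats::runif(1)
    syn[s, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
  }
  colnames(syn) <- colnames(x)
  minority_label <- enc$levels[if (minority_code == -1) 1 else 2]
  out$x <- rbind(x, syn)
  out$y <- c(as.character(y), rep(minority_label, n_syn))
  out$provenance <- c(rep("original", nrow(x)), rep("synthetic", n_syn))
  out
}
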