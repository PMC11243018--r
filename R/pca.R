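#' Principal component analysis with a Hotelling T2 ellipse
#'
#' SVD-based PCA on an already scaled matrix. Alongside scores, loadings and
#' the per-component explained X variance, the 95% Hotelling T2 confidence
#' ellipse of the first two components is returned, as drawn on
#' chemometrics score plots.
#'
#' @param x a [scale_matrix()] result (or plain matrix, samples in rows,
#'   assumed centered).
#' @param n_components number of components (<= min(samples - 1,
#'   variables)).
#' @param conf confidence level of the ellipse.
#' @return A `pca_model`: `scores`, `loadings`, `r2x` (per component),
#'   `ellipse` (semi-axis lengths `a`, `b` for components 1-2).
#' @export
pca <- function(x, n_components = 2, conf = 0.95) {
  m <- if (inherits(x, "scaled_matrix")) x$data else as.matrix(x)
  n <- nrow(m)
  if (n_components > min(n - 1, ncol(m)))
    stop("n_components exceeds min(samples - 1, variables)")
  sv <- svd(m, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  loadings <- sv$v
  colnames(loadings) <- colnames(scores)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  r2x <- sv$d[seq_len(n_components)]^2 / sum(m^2)
  ellipse <- NULL
  if (n_components >= 2 && n > 2) {
    # Hotelling T2 bound for 2 components at the requested confidence
    t2 <- 2 * (n - 1) / (n - 2) * stats::qf(conf, 2, n - 2)
    ellipse <- list(a = stats::sd(scores[, 1]) * sqrt(t2),
                    b = stats::sd(scores[, 2]) * sqrt(t2),
                    t2_crit = t2)
  }
  structure(list(scores = scores, loadings = loadings, r2x = r2x,
                 ellipse = ellipse),
            class = "pca_model")
}

#' Agglomerative hierarchical clustering of samples
#'
#' Thin wrapper over [stats::hclust()] on a sample distance matrix, with a
#' flat cut at `k`, used as the cluster-analysis diagnostic of group
#' structure.
#'
#' @param x a [scale_matrix()] result or matrix (samples in rows).
#' @param linkage one of `"ward.D2"`, `"average"`, `"complete"`, `"single"`.
#' @param metric `"euclidean"`, `"manhattan"` or `"correlation"`
#'   (1 - Pearson).
#' @param k number of flat clusters to cut (default 3).
#' @return list with the `hclust` `tree` and integer `labels` at `k`.
#' @export
hcluster <- function(x, linkage = "ward.D2", metric = "euclidean", k = 3) {
  m <- if (inherits(x, "scaled_matrix")) x$data else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples to cluster")
  linkage <- match.arg(linkage, c("ward.D2", "average", "complete", "single"))
  metric <- match.arg(metric, c("euclidean", "manhattan", "correlation"))
  d <- if (metric == "correlation")
    stats::as.dist(1 - stats::cor(t(m)))
  else
    stats::dist(m, method = metric)
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, labels = stats::cutree(tree, k = min(k, nrow(m))))
}
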