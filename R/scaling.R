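#' Center and scale a samples x variables matrix
#'
#' Column-wise centering with unit-variance, Pareto (divide by the square
#' root of the standard deviation) or no scaling. Constant columns are left
#' centered with a unit scale factor. The raw matrix and the scaling
#' statistics are retained so models can apply the same transform to new
#' samples (e.g. cross-validation folds).
#'
#' @param x numeric matrix, samples in rows.
#' @param mode one of `"uv"` (unit variance), `"pareto"`, `"none"`.
#' @return A `scaled_matrix`: list with `data` (transformed), `raw`,
#'   `center`, `scale`, `mode`.
#' @export
scale_matrix <- function(x, mode = c("uv", "pareto", "none")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sc <- switch(mode,
               uv = ifelse(sds == 0, 1, sds),
               pareto = ifelse(sds == 0, 1, sqrt(sds)),
               none = rep(1, ncol(x)))
  structure(list(data = sweep(sweep(x, 2, ctr), 2, sc, `/`),
                 raw = x, center = ctr, scale = sc, mode = mode),
            class = "scaled_matrix")
}

# apply a fitted scaling to new rows
apply_scaling <- function(sm, newx) {
  sweep(sweep(as.matrix(newx), 2, sm$center), 2, sm$scale, `/`)
}
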