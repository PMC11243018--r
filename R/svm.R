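#' RBF-kernel SVM model selection and cross-validated accuracy
#'
#' `grid_search_rbf()` trains a soft-margin RBF SVM for every (cost,
#' gamma) grid cell and scores it by stratified k-fold cross-validation
#' accuracy; the best cell is returned, ties broken by the smallest cost and
#' then the smallest gamma. `cv_accuracy()` reports the mean stratified
#' k-fold accuracy over several random repeats at fixed (c, g). SVM fits go
#' through [e1071::svm()] (libsvm); features are expected to be scaled by
#' the caller, so internal libsvm scaling is disabled.
#'
#' @param x numeric matrix, samples in rows (pre-scaled).
#' @param y two-class labels.
#' @param cost_grid,gamma_grid candidate penalty factors c and kernel
#'   widths g; the default grid is powers of two from 2^-10 to 2^10.
#' @param folds cross-validation folds (3 for tuning, 10 for accuracy).
#' @param seed integer seed driving fold assignment.
#' @return An `svm_tuning`: `best_cost`, `best_gamma`, `best_accuracy`
#'   (percent), and the full `grid` with per-cell accuracies.
#' @export
grid_search_rbf <- function(x, y,
                            cost_grid = 2^(-10:10),
                            gamma_grid = 2^(-10:10),
                            folds = 3, seed = 1L) {
  if (length(cost_grid) == 0 || length(gamma_grid) == 0)
    stop("empty tuning grid")
  x <- as.matrix(x)
  fold <- stratified_folds(y, folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    fold_accuracy(x, y, fold, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  best <- order(-grid$accuracy, grid$cost, grid$gamma)[1]
  structure(list(best_cost = grid$cost[best],
                 best_gamma = grid$gamma[best],
                 best_accuracy = grid$accuracy[best],
                 folds = folds, grid = grid),
            class = "svm_tuning")
}

#' @rdname grid_search_rbf
#' @param cost,gamma SVM penalty factor and RBF width to evaluate.
#' @param repeats number of random fold repeats (default 10).
#' @return `cv_accuracy()`: mean accuracy in percent over repeats x folds.
#' @export
cv_accuracy <- function(x, y, cost, gamma, folds = 10, repeats = 10,
                        seed = 1L) {
  x <- as.matrix(x)
  counts <- table(y)
  if (length(counts) != 2) stop("y must contain exactly 2 classes")
  if (folds > sum(counts))
    stop("more folds than samples: stratification infeasible")
  acc <- vapply(seq_len(repeats), function(r) {
    fold <- stratified_folds(y, folds, derive_seed(seed, r))
    fold_accuracy(x, y, fold, cost, gamma)
  }, numeric(1))
  mean(acc)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  local_rng(seed)
  fold <- integer(length(y))
  for (cls in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# percent accuracy of one fold schedule at fixed (cost, gamma)
fold_accuracy <- function(x, y, fold, cost, gamma) {
  y <- factor(as.character(y))
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("a training fold lost a class")
    m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    pred <- stats::predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  100 * correct / length(y)
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat(sprintf(
    "RBF SVM tuning: best c = %.4g, g = %.4g (%d-fold CV accuracy %.1f%%)\n",
    x$best_cost, x$best_gamma, x$folds, x$best_accuracy))
  invisible(x)
}
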