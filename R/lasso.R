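#' LASSO fit by coordinate descent
#'
#' Minimizes the squared-error L1 objective
#' `||y - b0 - X beta||^2 + lambda * ||beta||_1` (intercept unpenalized) by
#' cyclic coordinate descent. With this convention the whole coefficient
#' vector is exactly zero once `lambda >= 2 * max|X'(y - mean(y))|`, and on
#' an orthonormal design each coefficient is the soft-thresholded OLS
#' coefficient `S(x_j'y, lambda/2)`.
#'
#' @param X Numeric matrix (standardization is the caller's choice).
#' @param y Numeric response (0/1-encoded class labels in this pipeline).
#' @param lambda Penalty, >= 0.
#' @param tol Convergence tolerance on coefficient updates.
#' @param maxit Maximum coordinate-descent sweeps.
#' @return List with `intercept` and `beta`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-10, maxit = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stopf("non-finite values in X or y")
  if (lambda < 0) stopf("lambda must be >= 0")
  fit <- lasso_cd(X, y, lambda, tol = tol, maxit = maxit)
  fit$beta <- setNames(as.numeric(fit$beta), colnames(X))
  fit
}

#' Smallest penalty with an all-zero solution
#'
#' @inheritParams lasso_fit
#' @return `2 * max|X'(y - mean(y))|`.
#' @export
lasso_lambda_max <- function(X, y) {
  2 * max(abs(crossprod(as.matrix(X), y - mean(y))))
}

# Log-spaced penalty grid from lambda_max down.
lambda_grid <- function(X, y, n_lambda = 30, min_ratio = 0.01) {
  lmax <- lasso_lambda_max(X, y)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Pathwise LASSO over a penalty grid
#'
#' @inheritParams lasso_fit
#' @param lambdas Decreasing penalty sequence.
#' @return List `intercept` (vector), `beta` (p x n_lambda matrix).
#' @export
lasso_path <- function(X, y, lambdas, tol = 1e-7, maxit = 2000L) {
  X <- as.matrix(X)
  lambdas <- sort(lambdas, decreasing = TRUE)
  fit <- lasso_path_cd(X, y, lambdas, tol = tol, maxit = maxit)
  rownames(fit$beta) <- colnames(X)
  fit$lambdas <- lambdas
  fit
}

# Stratified fold ids (1..k) for a binary 0/1 response.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# Pick the penalty minimizing k-fold CV squared error over the grid.
# Assumes the caller set the RNG state (fold assignment draws from it).
choose_lambda_cv <- function(X, y, lambdas, k = 5) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  fold <- stratified_folds(y, k)
  err <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
    fit <- lasso_path(X[tr, , drop = FALSE], y[tr], lambdas)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2, fit$intercept, "+")
    err[f, ] <- colMeans((pred - y[!tr])^2)
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  lambdas[which.min(mean_err)]
}
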