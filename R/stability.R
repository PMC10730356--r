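#' Stability-selection configuration
#'
#' Controls the bootstrapped-LASSO feature selection and the Monte Carlo
#' cross-validation of the fused model: 500 bootstrap iterations, each
#' subsampling 50% of the training data without replacement
#' (class-stratified), keeping features selected in more than half of the
#' iterations; five Monte Carlo folds with patient-grouped 80/20 splits.
#'
#' The penalty used within each bootstrap is a design choice; four rules
#' are offered. The default, `support`, walks the penalty path from
#' `lambda_max` down and stops at the largest penalty whose support reaches
#' `support_q` features (default `ceiling(sqrt(p)/2)`), the classical
#' stability-selection device of capping the number of variables admitted
#' per subsample, which keeps the per-iteration selection sparse enough for
#' selection frequencies to separate signal from noise. `cv_min` picks the
#' penalty minimizing `inner_cv_folds`-fold CV squared error on the
#' bootstrap's subsample over a shared log-spaced grid (liberal: many noise
#' features ride along); `fixed` uses `fixed_lambda`; `max_path` scores
#' each feature by its maximum selection frequency over the whole grid.
#'
#' @param n_bootstrap Bootstrap iterations.
#' @param subsample_frac Fraction subsampled per iteration (0 < f < 1).
#' @param freq_threshold Selection-frequency threshold (features kept when
#'   frequency strictly exceeds it).
#' @param n_lambda,lambda_min_ratio Penalty grid: log-spaced from the
#'   training `lambda_max` down to `lambda_min_ratio` times it.
#' @param lambda_rule One of `support`, `cv_min`, `fixed`, `max_path`.
#' @param support_q Support cap for the `support` rule (default
#'   `ceiling(sqrt(p)/2)`).
#' @param fixed_lambda Penalty for the `fixed` rule.
#' @param inner_cv_folds Folds of the inner CV (rule `cv_min`).
#' @param cv_folds Monte Carlo cross-validation folds.
#' @param cv_test_frac Held-out fraction per Monte Carlo fold.
#' @param grouping `patient` (default; sibling ROIs never straddle
#'   train/test) or `roi`.
#' @param seed Integer seed.
#' @return Object of class `stability_config`.
#' @export
stability_config <- function(n_bootstrap = 500, subsample_frac = 0.5,
                             freq_threshold = 0.5, n_lambda = 30,
                             lambda_min_ratio = 0.01,
                             lambda_rule = c("support", "cv_min", "fixed",
                                             "max_path"),
                             support_q = NULL,
                             fixed_lambda = NULL, inner_cv_folds = 5,
                             cv_folds = 5, cv_test_frac = 0.2,
                             grouping = c("patient", "roi"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  grouping <- match.arg(grouping)
  if (subsample_frac <= 0 || subsample_frac >= 1)
    stopf("subsample_frac must lie in (0, 1)")
  if (freq_threshold < 0 || freq_threshold > 1)
    stopf("freq_threshold must lie in [0, 1]")
  if (n_bootstrap < 1) stopf("n_bootstrap must be >= 1")
  structure(list(n_bootstrap = n_bootstrap, subsample_frac = subsample_frac,
                 freq_threshold = freq_threshold, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_rule = lambda_rule, support_q = support_q,
                 fixed_lambda = fixed_lambda,
                 inner_cv_folds = inner_cv_folds, cv_folds = cv_folds,
                 cv_test_frac = cv_test_frac, grouping = grouping,
                 seed = as.integer(seed)),
            class = "stability_config")
}

# Class-stratified subsample (indices) of fraction f, each class >= 1.
stratified_subsample <- function(y, f) {
  unlist(lapply(split(seq_along(y), y), function(ix) {
    m <- max(1L, round(f * length(ix)))
    ix[sample.int(length(ix), m)]
  }), use.names = FALSE)
}

# Standardize columns to mean 0 / SD 1; zero-SD columns become all-zero.
standardize <- function(X, center = NULL, scale = NULL) {
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- Inf
  list(x = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Stability selection by bootstrapped LASSO
#'
#' Repeatedly subsamples `subsample_frac` of the samples without
#' replacement (class-stratified), standardizes the subsample, fits the
#' LASSO at the per-iteration penalty, and records which features carry
#' nonzero coefficients. A feature's selection frequency is the fraction of
#' iterations selecting it; features with frequency above `freq_threshold`
#' form the selected set.
#'
#' @param X Numeric matrix (one feature class), no missing values.
#' @param y Binary labels (0/1, logical, or two-level factor).
#' @param config A [stability_config()].
#' @return List `frequency` (named), `selected` (character), `lambdas`
#'   (per-iteration penalties, `NA` for rule `max_path`), `config`.
#' @export
stability_selection <- function(X, y, config = stability_config()) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) != 2 || min(table(y)) < 2)
    stopf("need >= 2 samples per class")
  if (any(!is.finite(X))) stopf("X contains non-finite values")
  p <- ncol(X)
  cn <- colnames(X) %||% as.character(seq_len(p))
  with_seed(config$seed, {
    sfull <- standardize(X)
    grid <- lambda_grid(sfull$x, y, config$n_lambda,
                        config$lambda_min_ratio)
    hits <- if (config$lambda_rule == "max_path")
      matrix(0, p, length(grid)) else numeric(p)
    lambdas <- rep(NA_real_, config$n_bootstrap)
    for (b in seq_len(config$n_bootstrap)) {
      for (try in 1:50) {
        sub <- stratified_subsample(y, config$subsample_frac)
        if (length(unique(y[sub])) == 2) break
        if (try == 50) stopf("could not draw a two-class subsample")
      }
      Xb <- standardize(X[sub, , drop = FALSE])$x
      yb <- y[sub]
      if (config$lambda_rule == "max_path") {
        fit <- lasso_path(Xb, yb, grid)
        hits <- hits + (abs(fit$beta) > 1e-12)
      } else if (config$lambda_rule == "support") {
        q <- config$support_q %||% ceiling(sqrt(p) / 2)
        fit <- lasso_path(Xb, yb, grid)
        supp <- abs(fit$beta) > 1e-12
        sizes <- colSums(supp)
        idx <- which(sizes >= q)
        idx <- if (length(idx) > 0) idx[1] else length(grid)
        lambdas[b] <- fit$lambdas[idx]
        hits <- hits + supp[, idx]
      } else {
        lam <- if (config$lambda_rule == "fixed") {
          config$fixed_lambda %||% stopf("fixed_lambda not set")
        } else {
          choose_lambda_cv(Xb, yb, grid, k = config$inner_cv_folds)
        }
        lambdas[b] <- lam
        fit <- lasso_fit(Xb, yb, lam, tol = 1e-8, maxit = 10000L)
        hits <- hits + (abs(fit$beta) > 1e-12)
      }
    }
    freq <- if (config$lambda_rule == "max_path")
      apply(hits / config$n_bootstrap, 1, max)
    else hits / config$n_bootstrap
    names(freq) <- cn
    list(frequency = freq,
         selected = cn[freq > config$freq_threshold],
         lambdas = lambdas, config = config)
  })
}
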