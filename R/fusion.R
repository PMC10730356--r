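# Ridge-penalized logistic regression by IRLS (intercept unpenalized);
# numeric stabilizer for separable late-fusion fits.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1) + pen
    g <- crossprod(X1, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Late-fusion logistic model
#'
#' Maximum-likelihood logistic regression on the union of the features
#' selected per class by stability selection (unpenalized). Perfect
#' separation triggers a ridge-stabilized fit with a warning; an empty
#' feature set yields a degenerate intercept-only model scoring the
#' training prevalence.
#'
#' @param X Matrix of selected features (may have zero columns).
#' @param y Binary labels.
#' @param weights Optional observation weights (e.g., exact class
#'   proportions on a covariate grid for consistency checks).
#' @return Object of class `fusion_model` with `coef`, `features`, `type`.
#' @export
late_fusion_fit <- function(X, y, weights = NULL) {
  # class labels are recoded to 0/1; numeric responses already in [0, 1]
  # (e.g., exact class proportions with weights) pass through unchanged
  if (!is.numeric(y)) y <- as.integer(as.factor(y)) - 1L
  if (any(y < 0 | y > 1)) stopf("y must be binary labels or proportions")
  X <- as.matrix(X)
  if (ncol(X) == 0) {
    prev <- if (is.null(weights)) mean(y) else sum(weights * y) / sum(weights)
    return(structure(list(coef = c(intercept = qlogis(min(max(prev, 1e-12),
                                                          1 - 1e-12))),
                          features = character(0), type = "intercept",
                          prevalence = prev),
                     class = "fusion_model"))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- NULL
  separated <- FALSE
  withCallingHandlers(
    fit <- glm.fit(Xd, y, family = binomial(),
                   weights = weights %||% rep(1, length(y))),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged || any(!is.finite(coef(fit))) ||
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)) {
    warnf("separation in late-fusion fit; using ridge-stabilized estimate")
    b <- ridge_logistic(X, y)
    cf <- setNames(b, c("intercept", colnames(X)))
    return(structure(list(coef = cf, features = colnames(X), type = "ridge"),
                     class = "fusion_model"))
  }
  cf <- coef(fit)
  names(cf) <- c("intercept", colnames(X))
  structure(list(coef = cf, features = colnames(X), type = "glm"),
            class = "fusion_model")
}

#' @export
predict.fusion_model <- function(object, newdata = NULL, ...) {
  if (object$type == "intercept") {
    n <- if (is.null(newdata)) 1L else nrow(as.matrix(newdata))
    return(rep(plogis(object$coef[["intercept"]]), n))
  }
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  drop(plogis(object$coef[["intercept"]] +
                X %*% object$coef[object$features]))
}

# Impute missing entries with training-column medians; all-missing columns
# fall back to 0.
impute_medians <- function(train, test = NULL) {
  med <- apply(train, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- med[j]
    }
    m
  }
  list(train = fill(train), test = if (is.null(test)) NULL else fill(test),
       medians = med)
}

# Patient-grouped train/test split; guarantees both classes in train and
# in test (bounded retries). Returns logical test-row mask.
grouped_split <- function(patient, y, test_frac) {
  pats <- unique(patient)
  pat_y <- vapply(pats, function(p) y[match(p, patient)], 0L)
  for (try in 1:100) {
    n_test <- max(1L, round(test_frac * length(pats)))
    test_p <- sample(pats, n_test)
    test <- patient %in% test_p
    if (length(unique(y[!test])) == 2 && length(unique(y[test])) == 2)
      return(test)
  }
  stopf("could not build a grouped split with both classes on each side")
}

# Stability selection per feature class + fused fit on given training rows.
fit_fold <- function(x, col_info, y, train, config, seed) {
  imp <- impute_medians(x[train, , drop = FALSE],
                        x[!train, , drop = FALSE])
  classes <- unique(col_info$feature_class)
  sel <- list(); freq <- list()
  for (k in seq_along(classes)) {
    cols <- which(col_info$feature_class == classes[k])
    cfg_k <- config
    cfg_k$seed <- derive_seed(seed, k)
    ss <- stability_selection(imp$train[, cols, drop = FALSE], y[train],
                              cfg_k)
    sel[[classes[k]]] <- ss$selected
    freq[[classes[k]]] <- ss$frequency
  }
  chosen <- unlist(sel, use.names = FALSE)
  std <- standardize(imp$train[, chosen, drop = FALSE])
  model <- late_fusion_fit(std$x, y[train])
  test_scores <- NULL
  if (any(!train)) {
    xt <- sweep(sweep(imp$test[, chosen, drop = FALSE], 2, std$center),
                2, std$scale, "/")
    test_scores <- predict(model, xt)
  }
  list(selected = sel, frequency = freq, model = model,
       test_scores = test_scores)
}

#' Monte Carlo cross-validation of the late-fusion classifier
#'
#' Runs `cv_folds` Monte Carlo folds. Each fold draws a grouped train/test
#' split (patients never straddle the split under the default grouping),
#' imputes missing features with training medians, runs stability selection
#' per feature class on the training rows only, fits the fused logistic
#' model on the union of selected features, and scores the held-out ROIs.
#' Out-of-fold scores are pooled over folds for the AUC, its bootstrap CI
#' and Mann-Whitney p-value. The final feature list comes from stability
#' selection on the entire dataset.
#'
#' @param fm A [feature_matrix] with `grade` in its `row_info`.
#' @param config A [stability_config()].
#' @param positive_class Level of `grade` treated as 1.
#' @return Object of class `stability_result`: `auc` (list from
#'   [auroc()]), `fold_scores` (pooled data.frame), `final` (full-data
#'   selection frequencies, selected sets and fused model), `config`.
#' @export
monte_carlo_cv <- function(fm, config = stability_config(),
                           positive_class = "high") {
  x <- fm$x
  y <- as.integer(fm$row_info$grade == positive_class)
  group <- if (config$grouping == "patient") fm$row_info$patient_id
           else fm$row_info$roi_id
  if (length(unique(group[y == 1])) < 2 || length(unique(group[y == 0])) < 2)
    stopf("need >= 2 groups per class for grouped splitting")
  scores_list <- vector("list", config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    seed_f <- derive_seed(config$seed, 1000 + f)
    test <- with_seed(seed_f, grouped_split(group, y, config$cv_test_frac))
    fold <- fit_fold(x, fm$col_info, y, !test, config, seed_f)
    scores_list[[f]] <- data.frame(
      fold = f, roi_id = fm$row_info$roi_id[test],
      score = fold$test_scores,
      # centering at the fold's training prevalence aligns score scales
      # across folds before pooling; a fold whose model is intercept-only
      # then contributes exact ties instead of a spurious prevalence
      # ranking
      score_centered = fold$test_scores - mean(y[!test]),
      label = y[test],
      stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, scores_list)
  auc <- auroc(pooled$score_centered, pooled$label,
               seed = derive_seed(config$seed, 424242L))
  final <- fit_fold(x, fm$col_info, y, rep(TRUE, nrow(x)), config,
                    derive_seed(config$seed, 888888L))
  structure(list(auc = auc, fold_scores = pooled,
                 final = list(frequency = final$frequency,
                              selected = final$selected,
                              model = final$model),
                 config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Monte Carlo CV: pooled AUC = %.3f [%.3f, %.3f], p = %.3g\n",
              x$auc$auc, x$auc$ci[1], x$auc$ci[2], x$auc$p))
  sel <- unlist(x$final$selected, use.names = FALSE)
  cat(sprintf("final model: %d selected features\n", length(sel)))
  invisible(x)
}
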