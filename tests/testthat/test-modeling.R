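test_that("the LASSO shrinks to zero at lambda_max and to OLS at lambda -> 0", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(5)
  lmax <- lasso_lambda_max(X, y)
  expect_true(all(lasso_fit(X, y, lmax)$beta == 0))
  expect_true(all(lasso_fit(X, y, lmax * 2)$beta == 0))
  expect_true(any(lasso_fit(X, y, lmax * 0.9)$beta != 0))
  # lambda -> 0 recovers least squares
  ols <- coef(lm(y ~ X))
  f <- lasso_fit(X, y, 1e-10)
  expect_equal(unname(f$beta), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(f$intercept, unname(ols[1]), tolerance = 1e-4)
  expect_error(lasso_fit(X, c(y[-1], NA), 1), "non-finite")
  expect_error(lasso_fit(X, y, -1), "lambda")
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(7)
  n <- 40; p <- 8
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n), scale = FALSE)))
  colnames(Q) <- paste0("q", 1:p)
  y <- rnorm(n)
  z <- drop(crossprod(Q, y))  # OLS coefficients under orthonormality
  for (lam in c(0.05, 0.2, 1)) {
    soft <- sign(z) * pmax(abs(z) - lam / 2, 0)
    f <- lasso_fit(Q, y, lam, tol = 1e-12)
    expect_lt(max(abs(f$beta - soft)), 1e-6)
  }
})

test_that("the coordinate-descent solution agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 30; p <- 12
  X <- scale(matrix(rnorm(n * p), n))
  y <- rbinom(n, 1, 0.5)
  lam <- lasso_lambda_max(X, y) * 0.3
  mine <- lasso_fit(X, y, lam, tol = 1e-12)
  ref <- glmnet::glmnet(X, y, family = "gaussian",
                        lambda = lam / (2 * n), standardize = FALSE,
                        thresh = 1e-14)
  expect_lt(max(abs(mine$beta - as.numeric(ref$beta))), 1e-5)
})

test_that("a perfect predictor reaches selection frequency 1", {
  set.seed(3)
  n <- 24
  y <- rep(0:1, n / 2)
  X <- cbind(target = y + 0, matrix(rnorm(n * 5), n))
  colnames(X)[-1] <- paste0("n", 1:5)
  ss <- stability_selection(X, y, stability_config(n_bootstrap = 50,
                                                   seed = 2))
  expect_equal(unname(ss$frequency["target"]), 1)
  expect_true("target" %in% ss$selected)
})

test_that("pure-noise designs select almost nothing", {
  sel_sizes <- vapply(c(19, 29), function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 40), 60)
    colnames(X) <- paste0("f", 1:40)
    y <- rep(0:1, 30)
    ss <- stability_selection(X, y, stability_config(n_bootstrap = 100,
                                                     seed = s))
    length(ss$selected)
  }, 1)
  expect_true(all(sel_sizes <= 2))  # 5% of 40
})

test_that("stability selection is reproducible and validates inputs", {
  set.seed(5)
  X <- matrix(rnorm(30 * 10), 30)
  colnames(X) <- paste0("f", 1:10)
  y <- rep(0:1, 15)
  cfg <- stability_config(n_bootstrap = 40, seed = 9)
  expect_identical(stability_selection(X, y, cfg)$frequency,
                   stability_selection(X, y, cfg)$frequency)
  expect_error(stability_selection(X, rep(0, 30), cfg), "2 samples")
  X[1, 1] <- NA
  expect_error(stability_selection(X, y, cfg), "non-finite")
  expect_error(stability_config(subsample_frac = 1.2), "subsample_frac")
  expect_error(stability_config(n_bootstrap = 0), "n_bootstrap")
})

test_that("late fusion degenerates gracefully and recovers known log-odds", {
  # zero features: intercept-only at the prevalence
  y <- c(rep(1, 3), rep(0, 7))
  m0 <- late_fusion_fit(matrix(0, 10, 0), y)
  expect_equal(m0$type, "intercept")
  expect_equal(unname(predict(m0, matrix(0, 4, 0))), rep(0.3, 4))

  # a perfectly separating feature triggers the ridge fallback and still
  # ranks the training data perfectly
  Xs <- matrix(c(rep(-2, 5), rep(2, 5)), ncol = 1,
               dimnames = list(NULL, "sep"))
  ys <- rep(0:1, each = 5)
  expect_warning(ms <- late_fusion_fit(Xs, ys), "separation")
  expect_equal(ms$type, "ridge")
  expect_equal(auroc(predict(ms, Xs), ys, n_boot = 10)$auc, 1)

  # consistency: fitting exact class probabilities on a covariate grid
  # returns the generating coefficients
  grid <- as.matrix(expand.grid(x1 = seq(-2, 2, 0.5),
                                x2 = seq(-2, 2, 0.5)))
  b <- c(0.5, -1, 2)
  pr <- plogis(b[1] + grid %*% b[2:3])
  mfit <- suppressWarnings(late_fusion_fit(grid, drop(pr),
                                           weights = rep(50, nrow(grid))))
  expect_lt(max(abs(mfit$coef - b)), 1e-3)
})

test_that("Monte Carlo CV is deterministic and leak-free", {
  fm <- simulate_feature_matrix(n_patients = 12, n_features = 24,
                                n_informative = 4, seed = 44)
  cfg <- stability_config(n_bootstrap = 30, seed = 15)
  r1 <- suppressWarnings(monte_carlo_cv(fm, cfg))
  r2 <- suppressWarnings(monte_carlo_cv(fm, cfg))
  expect_identical(r1$auc$auc, r2$auc$auc)
  expect_identical(r1$final$selected, r2$final$selected)
  expect_identical(r1$fold_scores, r2$fold_scores)

  # leakage canary: corrupting held-out rows must not change what a fold
  # selects or fits (training-only standardization/imputation/selection)
  y <- as.integer(fm$row_info$grade == "high")
  train <- !(fm$row_info$patient_id %in% c("SIM_P01", "SIM_P12"))
  x2 <- fm$x
  x2[!train, ] <- 1e6
  f1 <- suppressWarnings(spatzone:::fit_fold(fm$x, fm$col_info, y, train,
                                             cfg, 77))
  f2 <- suppressWarnings(spatzone:::fit_fold(x2, fm$col_info, y, train,
                                             cfg, 77))
  expect_identical(f1$frequency, f2$frequency)
  expect_identical(f1$model$coef, f2$model$coef)
})

test_that("grouped splits never separate a patient's ROIs", {
  fm <- simulate_feature_matrix(n_patients = 10, n_features = 8,
                                n_informative = 0, seed = 3)
  y <- as.integer(fm$row_info$grade == "high")
  for (s in 1:5) {
    test <- spatzone:::with_seed(s, spatzone:::grouped_split(
      fm$row_info$patient_id, y, 0.2))
    split_pats <- tapply(test, fm$row_info$patient_id,
                         function(v) length(unique(v)))
    expect_true(all(split_pats == 1))
  }
})

test_that("AUC matches pair counting, with ties and bootstrap CI", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                     n_boot = 10)$auc, 0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3),
                     n_boot = 10)$auc, 1)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5), n_boot = 10)$auc, 0.5)
  r <- auroc(rnorm(40), rbinom(40, 1, 0.5), n_boot = 200, seed = 4)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  # independent cross-check of the rank formulation
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(lb, sc)))
  mine <- auroc(sc, lb, n_boot = 10)$auc
  expect_equal(max(mine, 1 - mine), max(ref, 1 - ref), tolerance = 1e-12)
})

test_that("Mann-Whitney matches exact enumeration and wilcox.test", {
  # identical samples: centered U, exact p = 1
  mw <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(mw$p, 1)
  # x=(1,2), y=(3,4): U = 0, two-sided exact p = 2 * (1/6)
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  # against wilcox.test where both use the normal approximation (no ties)
  set.seed(8)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  mine <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney has power ~1 for a two-SD shift at n = 30", {
  set.seed(12)
  rej <- mean(replicate(300, {
    mann_whitney(rnorm(30), rnorm(30, 2))$p < 0.05
  }))
  expect_gte(rej, 0.99)
})

test_that("the univariate screen flags planted effects, not constants", {
  set.seed(21)
  n <- 40
  g <- rep(0:1, n / 2)
  x <- cbind(planted = g * 1.5 + rnorm(n), const = rep(2, n),
             noise = rnorm(n))
  scr <- univariate_screen(x, g)
  expect_true(scr$flagged[scr$feature == "planted"])
  expect_equal(scr$p[scr$feature == "const"], 1)
  # null calibration, roughly: ~5% of pure-noise features flagged
  xn <- matrix(rnorm(n * 400), n)
  colnames(xn) <- paste0("f", 1:400)
  frac <- mean(univariate_screen(xn, g)$flagged)
  expect_gt(frac, 0.01); expect_lt(frac, 0.10)
})
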