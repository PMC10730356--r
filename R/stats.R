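#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. `U` counts pairs where an
#' `x` value exceeds a `y` value (ties count 1/2). When the pooled size is
#' at most `exact_max` the p-value is computed by exact enumeration of all
#' group assignments of the pooled values (ties handled naturally), with
#' the two-sided p defined as `min(1, 2 * min(Pr(U <= u), Pr(U >= u)))`.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param exact_max Pooled-size cutoff for exact enumeration.
#' @return List with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= exact_max) {
    idx <- combn(N, n1)
    us <- apply(idx, 2, function(ii)
      sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu)
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(U = U, p = p)
}

#' Area under the ROC curve with bootstrap CI
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction, a
#' stratified bootstrap percentile confidence interval, and a two-sided
#' Mann-Whitney p-value for the separation of the score distributions.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1, logical, or two-level factor; the
#'   larger level is the positive class).
#' @param n_boot Bootstrap replicates for the CI.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return List `auc`, `ci` (length 2), `p`, `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = 1) {
  lab <- as.integer(as.factor(labels)) - 1L
  if (length(unique(lab)) != 2) stopf("both classes must be present")
  pos <- scores[lab == 1]; neg <- scores[lab == 0]
  auc_of <- function(p, n) {
    r <- rank(c(p, n))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }
  auc <- auc_of(pos, neg)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      auc_of(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    }, 1)
    quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  p <- mann_whitney(pos, neg)$p
  list(auc = auc, ci = ci, p = p, n_pos = length(pos), n_neg = length(neg))
}

#' Univariate feature screen
#'
#' Per-feature two-sided Mann-Whitney test at ROI level against a binary
#' grouping (grade, recurrence, mortality), uncorrected for multiple
#' testing. Features with p below `alpha` are flagged; cross-tabulating
#' flags from different groupings identifies features associated with both
#' grade and outcome.
#'
#' @param x Matrix ROI x feature (e.g., the model features of a
#'   [feature_matrix]).
#' @param group Binary grouping vector.
#' @param alpha Flagging threshold.
#' @return Data.frame `feature`, `U`, `p`, `flagged`.
#' @export
univariate_screen <- function(x, group, alpha = 0.05) {
  x <- as.matrix(x)
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2) stopf("grouping must be binary")
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    ok <- is.finite(v)
    mw <- mann_whitney(v[ok & g == 1], v[ok & g == 0])
    data.frame(feature = colnames(x)[j] %||% as.character(j),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$p < alpha
  out
}
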