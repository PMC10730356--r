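#' Coefficient of variation
#'
#' Sample SD divided by mean. Undefined (returned as `NA`) when the mean is
#' zero; requires at least two values.
#'
#' @param values Numeric vector, length >= 2.
#' @return Scalar CV, or `NA` when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stopf("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}

#' Intrapatient coefficient of variation
#'
#' CV of a per-ROI feature across the ROIs of each patient, one value per
#' patient. Patients contributing fewer than two ROIs are skipped with a
#' warning.
#'
#' @param values Per-ROI feature values.
#' @param patient Patient id per ROI.
#' @return Named numeric vector of per-patient CVs.
#' @export
intrapatient_cv <- function(values, patient) {
  stopifnot(length(values) == length(patient))
  counts <- table(patient)
  few <- names(counts)[counts < 2]
  if (length(few) > 0)
    warnf("skipping %d patient(s) with < 2 ROIs", length(few))
  keep <- !(patient %in% few)
  vapply(split(values[keep], patient[keep]), coefficient_of_variation, 1)
}

#' Interpatient coefficient of variation
#'
#' Randomly selects one ROI per patient (seeded) and computes the CV of the
#' feature across patients. Optionally averages over `n_draws` repeated
#' selections to reduce Monte-Carlo noise (a single draw is the default).
#'
#' @param values Per-ROI feature values.
#' @param patient Patient id per ROI.
#' @param seed Integer seed for the ROI draw.
#' @param n_draws Number of repeated draws to average over.
#' @return Scalar CV (mean over draws).
#' @export
interpatient_cv <- function(values, patient, seed = 1, n_draws = 1) {
  stopifnot(length(values) == length(patient))
  pats <- unique(patient)
  if (length(pats) < 2) stopf("interpatient CV requires >= 2 patients")
  with_seed(seed, {
    cvs <- vapply(seq_len(n_draws), function(d) {
      pick <- vapply(split(seq_along(values), patient),
                     function(ix) ix[sample.int(length(ix), 1)], 1L)
      coefficient_of_variation(values[pick])
    }, 1)
    mean(cvs)
  })
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Returns `NA` with a
#' warning when either input has zero variance.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("zero-variance input to spearman_correlation")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Reproducibility correlations before and after spatial subsetting
#'
#' Two Fig 4-style reproducibility readouts computed on matched feature
#' tables from two cohorts (or one cohort's patients):
#' (a) inter-cohort: Spearman correlation of per-cohort feature means,
#' matched by feature name; (b) intrapatient: Spearman correlation over all
#' pooled within-patient ROI pairs (each pair of ROIs from one patient
#' contributes the points (value in ROI a, value in ROI b) for every
#' feature). Both are computed on the `before` table (e.g., raw counts) and
#' the `after` table (e.g., zonal densities).
#'
#' @param before,after Matrices ROI x feature (same rows; columns matched
#'   by name between cohorts).
#' @param patient Patient id per ROI.
#' @param cohort Cohort id per ROI (two cohorts for the inter-cohort
#'   readout).
#' @return List with `inter_cohort` and `intrapatient`, each holding
#'   `before` and `after` correlations.
#' @export
reproducibility_correlations <- function(before, after, patient, cohort) {
  inter <- function(m) {
    cos <- unique(cohort)
    if (length(cos) != 2) return(NA_real_)
    m1 <- colMeans(m[cohort == cos[1], , drop = FALSE], na.rm = TRUE)
    m2 <- colMeans(m[cohort == cos[2], , drop = FALSE], na.rm = TRUE)
    m2 <- m2[names(m1)]
    spearman_correlation(m1, m2)
  }
  intra <- function(m) {
    xs <- c(); ys <- c()
    for (p in unique(patient)) {
      rows <- which(patient == p)
      if (length(rows) < 2) next
      prs <- combn(rows, 2)
      for (q in seq_len(ncol(prs))) {
        xs <- c(xs, m[prs[1, q], ])
        ys <- c(ys, m[prs[2, q], ])
      }
    }
    spearman_correlation(xs, ys)
  }
  list(inter_cohort = list(before = inter(before), after = inter(after)),
       intrapatient = list(before = intra(before), after = intra(after)))
}

#' Cohort-level CV report for one feature table
#'
#' Intrapatient CVs (per patient) and the interpatient CV for every column
#' of a feature table.
#'
#' @param x Matrix ROI x feature.
#' @param patient Patient id per ROI.
#' @param seed Seed for the interpatient ROI draw.
#' @param n_draws Draws for [interpatient_cv()].
#' @return List with `intrapatient` (feature x patient matrix) and
#'   `interpatient` (named vector).
#' @export
cv_report <- function(x, patient, seed = 1, n_draws = 1) {
  intra <- t(apply(x, 2, function(v) intrapatient_cv(v, patient)))
  inter <- apply(x, 2, function(v)
    interpatient_cv(v, patient, seed = seed, n_draws = n_draws))
  list(intrapatient = intra, interpatient = inter, seed = seed)
}
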