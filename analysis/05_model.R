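#!/usr/bin/env Rscript
# Grade classification on the image-derived feature matrix: per-class
# stability-selection LASSO, late-fusion logistic regression, Monte Carlo
# cross-validation with pooled AUROC, and the univariate screen of the
# final model features. Writes results/model.json.

library(spatzone)

fm <- read_feature_matrix("results/features")
cat(sprintf("Feature matrix: %d ROIs x %d features\n", nrow(fm$x),
            ncol(fm$x)))

cfg <- stability_config(n_bootstrap = 200, seed = 3003)
cat("Running 5-fold Monte Carlo CV with stability selection per class\n")
cat("(200 bootstrap subsamples per class and fold)...\n")
res <- suppressWarnings(monte_carlo_cv(fm, cfg))
print(res)

sel <- unlist(res$final$selected, use.names = FALSE)
cat("\nFinal selected features (full-data stability selection):\n")
for (s in sel) cat("  ", s, "\n")
cat("\nSelected per class:\n")
for (cl in names(res$final$selected))
  cat(sprintf("  %-13s %d\n", cl, length(res$final$selected[[cl]])))

# univariate screen of the model features at ROI level (uncorrected)
scr <- univariate_screen(fm$x[, sel, drop = FALSE],
                         fm$row_info$grade == "high")
scr <- scr[order(scr$p), ]
cat("\nUnivariate Mann-Whitney screen of model features (ROI level):\n")
print(head(scr, 10), row.names = FALSE, digits = 3)
cat(sprintf("%d of %d model features have p < 0.05 (uncorrected)\n",
            sum(scr$flagged), nrow(scr)))

out <- list(auc = res$auc$auc, ci = res$auc$ci, p = res$auc$p,
            n_selected = length(sel), selected = sel,
            univariate = scr, seed = cfg$seed)
jsonlite::write_json(out, "results/model.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")
cat("Report written to results/model.json\n")
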