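test_that("tumor mask fractions hit their targets", {
  expect_equal(mean(generate_tumor_mask(c(60, 80), 0, seed = 1)), 0)
  expect_equal(mean(generate_tumor_mask(c(60, 80), 1, seed = 1)), 1)
  m <- generate_tumor_mask(c(500, 1000), 0.5, seed = 7)
  expect_equal(length(m), 500000)
  f <- sum(m) / 500000
  expect_gte(f, 0.45); expect_lte(f, 0.55)
  expect_error(generate_tumor_mask(c(60, 80), 1.2, seed = 1), "fraction")
  # deterministic given seed
  expect_identical(m, generate_tumor_mask(c(500, 1000), 0.5, seed = 7))
})

test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(n_patients = 2, roi_shape = c(120, 200), seed = 31)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$cells, co2$cells)
  expect_identical(co1$zones, co2$zones)
})

test_that("a stroma-only population never appears near or inside tumor", {
  pops <- default_populations()[1, ]
  pops$name <- "stroma_only"
  pops$density_stroma <- 150; pops$density_front <- 0; pops$density_core <- 0
  mu <- default_marker_mu()[1, , drop = FALSE]
  rownames(mu) <- "stroma_only"
  cfg <- cohort_config(n_patients = 2, roi_shape = c(200, 300),
                       populations = pops, marker_mu = mu,
                       grade_effects = list(), seed = 8)
  co <- generate_cohort(cfg)
  expect_true(all(co$cells$dist_border > 20))
  expect_true(all(co$cells$zone == "stroma"))
})

test_that("realized per-zone counts are calibrated to the point-process intensity", {
  # 50 single-ROI patients; expected count per zone = density * zone area
  # (patient/ROI lognormal factors have mean 1)
  pops <- default_populations()[c(5, 9), ]
  cfg <- cohort_config(n_patients = 50, rois_per_patient = 1,
                       roi_shape = c(250, 250),
                       tumor_fraction_range = c(0.4, 0.4),
                       populations = pops,
                       marker_mu = default_marker_mu()[pops$name, ],
                       grade_effects = list(), intrapatient_corr = 0,
                       seed = 77)
  co <- generate_cohort(cfg)
  dl <- zonal_density(co$cells, co$zones, pops$name)
  for (p in seq_len(nrow(pops))) {
    dens <- c(pops$density_stroma[p], pops$density_front[p],
              pops$density_core[p])
    for (zi in 1:3) {
      zone <- c("stroma", "front", "core")[zi]
      if (dens[zi] == 0) next
      area <- co$zones[[paste0("area_", zone)]]
      expected <- sum(dens[zi] * area)
      if (expected < 100) next  # Poisson noise alone exceeds the band
      observed <- sum(dl$count[dl$population == pops$name[p] &
                                 dl$zone == zone])
      expect_lt(abs(observed - expected) / expected, 0.10)
    }
  }
})

test_that("plant_effects is the identity for empty or zero effects", {
  co <- shared_cohort()
  cells <- co$cells
  expect_identical(plant_effects(cells, list()), cells)
  ef0 <- list(effect_spec("function", "front", "cd8_t", "pSTAT1", 0))
  expect_identical(plant_effects(cells, ef0), cells)
})

test_that("plant_effects validates populations, markers, and effect kinds", {
  cells <- shared_cohort()$cells
  expect_error(plant_effects(cells, list(
    effect_spec("function", "front", "nosuchpop", "pSTAT1", 1))),
    "unknown population")
  expect_error(plant_effects(cells, list(
    effect_spec("function", "front", "cd8_t", "nosuchmarker", 1))),
    "unknown marker")
  expect_error(plant_effects(cells, list(
    effect_spec("neighborhood", "front", "cd8_t", NULL, 1))),
    "not supported")
  expect_error(effect_spec("badclass", "front", "cd8_t"), "feature_class")
  expect_error(effect_spec("density", "badzone", "cd8_t"), "zone")
})

test_that("a planted functional effect is recovered at its nominal size", {
  # single function effect d = 1.0; recover the standardized mean
  # difference of the per-ROI mean marker from the generated cohort
  d_target <- 1.0
  cfg <- cohort_config(
    n_patients = 24, roi_shape = c(300, 600),
    grade_effects = list(effect_spec("function", "front", "cd8_t",
                                     "pSTAT1", d_target)),
    seed = 202)
  co <- generate_cohort(cfg)
  cells <- co$cells[co$cells$population == "cd8_t" &
                      co$cells$zone == "front", ]
  feat <- tapply(asinh(cells$raw_pSTAT1), cells$roi_id, mean)
  grade <- co$meta$grade[match(names(feat), co$meta$roi_id)]
  m1 <- mean(feat[grade == "high"]); m0 <- mean(feat[grade == "low"])
  sp <- sqrt((var(feat[grade == "high"]) + var(feat[grade == "low"])) / 2)
  d_hat <- (m1 - m0) / sp
  expect_lt(abs(d_hat - d_target), 0.25)
})

test_that("planted density effects shift per-ROI counts in the right direction", {
  cfg <- cohort_config(
    n_patients = 16, roi_shape = c(250, 500),
    grade_effects = list(effect_spec("density", "stroma", "fibroblast",
                                     effect_size = 1.2)),
    seed = 303)
  co <- generate_cohort(cfg)
  sel <- co$cells$population == "fibroblast" & co$cells$zone == "stroma"
  cnt <- table(factor(co$cells$roi_id[sel], levels = co$meta$roi_id))
  hi <- co$meta$grade == "high"
  expect_gt(mean(cnt[hi]), mean(cnt[!hi]))
})

test_that("mask rendering produces a valid label partition matching the table", {
  cfg <- cohort_config(n_patients = 1, rois_per_patient = 1,
                       roi_shape = c(150, 200), render_masks = TRUE,
                       keep_masks = TRUE, grade_effects = list(),
                       seed = 55)
  co <- generate_cohort(cfg)
  lab <- co$masks[[1]]$label_mask
  ids <- setdiff(unique(as.vector(lab)), 0L)
  expect_setequal(ids, co$cells$cell_id)
  # labels are a partition: every id appears as a connected pixel set >= 1
  expect_true(all(table(lab[lab > 0]) >= 1))
})

test_that("simulated feature matrices have the declared structure", {
  fm <- simulate_feature_matrix(n_patients = 8, n_features = 20,
                                n_informative = 4, seed = 5)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$x), c(24, 20))
  expect_equal(sum(fm$col_info$informative), 4)
  expect_setequal(unique(fm$col_info$feature_class),
                  c("density", "function", "metavariable", "neighborhood"))
  expect_identical(fm$x, simulate_feature_matrix(n_patients = 8,
                                                 n_features = 20,
                                                 n_informative = 4,
                                                 seed = 5)$x)
  # planted shift is close to nominal at large n
  big <- simulate_feature_matrix(n_patients = 200, n_features = 10,
                                 n_informative = 10, effect_size = 1.2,
                                 seed = 6)
  hi <- big$row_info$grade == "high"
  d_hat <- mean(colMeans(big$x[hi, ]) - colMeans(big$x[!hi, ]))
  expect_lt(abs(d_hat - 1.2), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(tumor_fraction_range = c(-0.1, 0.5)), "range")
  expect_error(cohort_config(rois_per_patient = 0), "rois_per_patient")
  expect_error(cohort_config(intrapatient_corr = 1.5), "intrapatient_corr")
  expect_equal(nrow(default_populations()), 15)
  expect_equal(length(functional_markers()), 14)
})
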