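test_that("tumor-covered fraction follows pixel arithmetic", {
  expect_equal(tumor_covered_fraction(zone_areas(matrix(FALSE, 100, 100))), 0)
  expect_equal(tumor_covered_fraction(zone_areas(matrix(TRUE, 100, 100))), 1)
  m <- matrix(FALSE, 500, 1000)
  m[201:300, 301:500] <- TRUE  # 100 x 200 rectangle
  expect_equal(tumor_covered_fraction(zone_areas(m)), 0.04)
})

toy_zones <- function(rois, stroma = 0.1, front = 0.05, core = 0.02) {
  n <- length(rois)
  data.frame(roi_id = rois, area_roi = rep(stroma + front + core, n),
             area_tumor = rep(front / 2 + core, n),
             area_stroma = rep(stroma, n), area_front = rep(front, n),
             area_core = rep(core, n))
}

test_that("zonal density is count over area, missing for zero-area zones", {
  cells <- data.frame(roi_id = rep("r1", 10), population = "P",
                      zone = "stroma")
  dl <- zonal_density(cells, toy_zones("r1"), populations = "P")
  expect_equal(dl$density[dl$zone == "stroma"], 100)
  expect_equal(dl$density[dl$zone == "front"], 0)
  # zero-area zone -> NA, not zero
  z0 <- toy_zones("r1"); z0$area_core <- 0
  dl0 <- zonal_density(cells, z0, populations = "P")
  expect_true(is.na(dl0$density[dl0$zone == "core"]))
  expect_equal(dl0$count[dl0$zone == "core"], 0)
})

test_that("zonal densities equal hand counts on a generated ROI", {
  co <- shared_cohort()
  roi <- co$meta$roi_id[1]
  cells <- co$cells[co$cells$roi_id == roi, ]
  dl <- zonal_density(cells, co$zones[co$zones$roi_id == roi, ],
                      default_populations()$name)
  for (i in sample(nrow(dl), 25)) {
    n_hand <- sum(cells$population == dl$population[i] &
                    cells$zone == dl$zone[i])
    expect_equal(dl$count[i], n_hand)
    if (dl$area[i] > 0) expect_equal(dl$density[i], n_hand / dl$area[i])
  }
})

test_that("the exclusion rule retains exactly the median-positive combos", {
  rois <- paste0("r", 1:5)
  dl <- expand.grid(roi_id = rois, population = c("A", "B"),
                    zone = c("stroma", "front", "core"),
                    stringsAsFactors = FALSE)
  dl$area <- 0.1
  dl$count <- 0L
  # A present in stroma of 3/5 ROIs (median > 0); B core in 2/5 (median 0)
  dl$count[dl$population == "A" & dl$zone == "stroma" &
             dl$roi_id %in% rois[1:3]] <- 5L
  dl$count[dl$population == "B" & dl$zone == "core" &
             dl$roi_id %in% rois[1:2]] <- 7L
  dl$density <- dl$count / dl$area
  rc <- retained_combos(dl)
  expect_true(rc$retained[rc$population == "A" & rc$zone == "stroma"])
  expect_false(rc$retained[rc$population == "B" & rc$zone == "core"])
  expect_equal(sum(rc$retained), 1)
})

test_that("functional and metavariable features equal group-by means", {
  set.seed(3)
  n <- 200
  cells <- data.frame(
    roi_id = sample(c("r1", "r2"), n, replace = TRUE),
    population = sample(c("A", "B"), n, replace = TRUE),
    zone = sample(c("stroma", "front", "core"), n, replace = TRUE),
    area = runif(n, 30, 100), eccentricity = runif(n),
    dist_border = runif(n, -15, 15),
    raw_M1 = rlnorm(n), raw_M2 = rlnorm(n))
  combos <- expand.grid(population = c("A", "B"),
                        zone = c("stroma", "front", "core"),
                        stringsAsFactors = FALSE)
  combos$retained <- TRUE
  rois <- c("r1", "r2")
  fn <- functional_features(cells, combos, rois, markers = c("M1", "M2"))
  mv <- spatial_metavariables(cells, combos, rois)
  for (i in seq_len(nrow(combos))) {
    sel <- cells$population == combos$population[i] &
      cells$zone == combos$zone[i]
    for (roi in rois) {
      srow <- sel & cells$roi_id == roi
      nm <- paste("function", combos$zone[i], combos$population[i], "M1",
                  sep = ":")
      expect_equal(fn$x[roi, nm],
                   if (any(srow)) mean(asinh(cells$raw_M1[srow]))
                   else NA_real_)
      nm_sz <- paste("metavariable", combos$zone[i], combos$population[i],
                     "size", sep = ":")
      expect_equal(mv$x[roi, nm_sz],
                   if (any(srow)) mean(cells$area[srow]) else NA_real_)
    }
  }
  # single cell -> feature equals its own value; two cells -> midpoint
  one <- cells[1, ]; one$raw_M1 <- sinh(2.5)
  two <- rbind(one, one); two$raw_M1 <- sinh(c(1, 3))
  f1 <- functional_features(one, combos, one$roi_id, markers = "M1")
  expect_equal(unname(f1$x[1, paste("function", one$zone, one$population,
                                    "M1", sep = ":")]), 2.5)
  f2 <- functional_features(two, combos, unique(two$roi_id), markers = "M1")
  expect_equal(unname(f2$x[1, paste("function", one$zone, one$population,
                                    "M1", sep = ":")]), 2)
})

test_that("border-distance metavariables are emitted for the front only", {
  co <- shared_cohort()
  cells <- co$cells
  dl <- zonal_density(cells, co$zones, default_populations()$name)
  mv <- spatial_metavariables(cells, retained_combos(dl), co$meta$roi_id)
  dist_cols <- mv$col_info[mv$col_info$marker == "border_dist", ]
  expect_true(nrow(dist_cols) > 0)
  expect_true(all(dist_cols$zone == "front"))
})

test_that("two nearby cells are each other's only neighborhood partner", {
  cells <- data.frame(roi_id = "r", cell_id = 1:2, x = c(0, 10), y = c(0, 0),
                      population = c("A", "B"), zone = "front",
                      area = c(1e-4, 1e-4))
  combos <- data.frame(population = c("A", "B"), zone = "front",
                       retained = TRUE)
  nb <- neighborhood_coefficients(cells, combos, "r",
                                  neighbor_config(distance_mode = "centroid"),
                                  populations = c("A", "B"))
  expect_equal(unname(nb$x["r", "neighborhood:front:A:B"]), 1)
  expect_equal(unname(nb$x["r", "neighborhood:front:B:A"]), 1)
  expect_equal(unname(nb$x["r", "neighborhood:front:A:A"]), 0)
})

test_that("isolated cells contribute nothing to neighborhood means", {
  cells <- data.frame(roi_id = "r", cell_id = 1:3,
                      x = c(0, 10, 500), y = c(0, 0, 500),
                      population = c("A", "B", "A"), zone = "front",
                      area = rep(1e-4, 3))
  combos <- data.frame(population = c("A", "B"), zone = "front",
                       retained = TRUE)
  nb <- neighborhood_coefficients(cells, combos, "r",
                                  neighbor_config(distance_mode = "centroid"),
                                  populations = c("A", "B"))
  # the far-away A cell has no neighbors; mean over A centers uses only
  # the first cell
  expect_equal(unname(nb$x["r", "neighborhood:front:A:B"]), 1)
})

test_that("neighborhood coefficients equal the O(n^2) oracle on fixtures", {
  pops <- c("A", "B", "C")
  for (seed in c(5, 11)) {
    set.seed(seed)
    n <- 30
    cells <- data.frame(
      roi_id = "r", cell_id = seq_len(n),
      x = runif(n, 0, 120), y = runif(n, 0, 80),
      population = sample(pops, n, replace = TRUE),
      zone = sample(c("stroma", "front", "core"), n, replace = TRUE),
      area = runif(n, 20, 80))
    combos <- expand.grid(population = pops,
                          zone = c("stroma", "front", "core"),
                          stringsAsFactors = FALSE)
    combos$retained <- TRUE
    # radius-corrected border surrogate (the default for point cells)
    nb <- neighborhood_coefficients(cells, combos, "r", neighbor_config(),
                                    populations = pops)
    oracle <- bf_neighborhood(cells, radii = sqrt(cells$area / pi),
                              populations = pops)
    # per-cell vectors are probability vectors
    for (pc in oracle$percell)
      if (!is.null(pc)) expect_equal(sum(pc), 1)
    for (key in names(oracle$means)) {
      zp <- strsplit(key, "|", fixed = TRUE)[[1]]
      for (partner in pops) {
        nm <- paste("neighborhood", zp[1], zp[2], partner, sep = ":")
        expect_equal(unname(nb$x["r", nm]),
                     unname(oracle$means[[key]][partner]),
                     tolerance = 1e-12)
      }
    }
    # centroid mode against the centroid oracle
    nbc <- neighborhood_coefficients(
      cells, combos, "r", neighbor_config(distance_mode = "centroid"),
      populations = pops)
    oc <- bf_neighborhood(cells, radii = NULL, populations = pops)
    for (key in names(oc$means)) {
      zp <- strsplit(key, "|", fixed = TRUE)[[1]]
      nm <- paste("neighborhood", zp[1], zp[2], pops[1], sep = ":")
      expect_equal(unname(nbc$x["r", nm]),
                   unname(oc$means[[key]][pops[1]]), tolerance = 1e-12)
    }
  }
})

test_that("exact border distances from label masks drive the neighbor graph", {
  # two 3x3 square cells with a 2-px gap: border distance 2, centroid 5
  lab <- matrix(0L, 20, 20)
  lab[5:7, 3:5] <- 1L
  lab[5:7, 8:10] <- 2L
  props <- spatzone:::region_props(lab)
  bnd <- spatzone:::label_boundary(lab)
  idx <- which(bnd, arr.ind = TRUE)
  boundaries <- lapply(split(seq_len(nrow(idx)), lab[bnd]), function(i)
    cbind((idx[i, 2] - 0.5), (idx[i, 1] - 0.5)))
  names(boundaries) <- names(split(seq_len(nrow(idx)), lab[bnd]))
  cells <- data.frame(roi_id = "r", cell_id = props$cell_id,
                      x = props$x, y = props$y,
                      population = c("A", "B"), zone = "front",
                      area = props$area)
  combos <- data.frame(population = c("A", "B"), zone = "front",
                       retained = TRUE)
  # border distance 2 <= 20: neighbors
  nb <- neighborhood_coefficients(cells, combos, "r",
                                  neighbor_config(max_dist = 20),
                                  boundaries = boundaries,
                                  populations = c("A", "B"))
  expect_equal(unname(nb$x["r", "neighborhood:front:A:B"]), 1)
  # with a 1-um cutoff they are not
  nb2 <- neighborhood_coefficients(cells, combos, "r",
                                   neighbor_config(max_dist = 1),
                                   boundaries = boundaries,
                                   populations = c("A", "B"))
  expect_true(is.na(nb2$x["r", "neighborhood:front:A:B"]))
})

test_that("the assembled matrix has the full four-class schema", {
  co <- shared_cohort()
  cells <- co$cells
  fm <- assemble_feature_matrix(cells, co$zones, co$meta)
  ci <- fm$col_info
  pops <- default_populations()$name
  # density class always spans the full 15 x 3 grid
  expect_equal(sum(ci$feature_class == "density"), 45)
  # schema oracle: enumerate expected columns from the retained set
  combos <- attr(fm, "combos")
  ret <- combos[combos$retained, ]
  expect_equal(sum(ci$feature_class == "function"), 14 * nrow(ret))
  n_front <- sum(ret$zone == "front")
  expect_equal(sum(ci$feature_class == "metavariable"),
               2 * nrow(ret) + n_front)
  n_nbr <- sum(vapply(c("stroma", "front", "core"), function(z)
    sum(ret$zone == z)^2, 1))
  expect_equal(sum(ci$feature_class == "neighborhood"), n_nbr)
  expect_false(anyDuplicated(ci$name) > 0)
  # deterministic column order
  fm2 <- assemble_feature_matrix(cells, co$zones, co$meta)
  expect_identical(colnames(fm$x), colnames(fm2$x))
  expect_identical(fm$x, fm2$x)
})

test_that("an empty cohort yields an empty matrix with the density schema", {
  cells <- data.frame(roi_id = character(0), population = character(0),
                      zone = character(0), area = numeric(0),
                      eccentricity = numeric(0), dist_border = numeric(0))
  zones <- toy_zones(character(0))
  meta <- data.frame(roi_id = character(0), patient_id = character(0),
                     cohort_id = character(0), grade = character(0))
  fm <- assemble_feature_matrix(cells, zones, meta)
  expect_equal(nrow(fm$x), 0)
  expect_equal(sum(fm$col_info$feature_class == "density"), 45)
})

test_that("duplicate feature names abort assembly", {
  expect_error(
    feature_matrix(matrix(0, 1, 2),
                   data.frame(name = c("a", "a"), feature_class = "density"),
                   data.frame(roi_id = "r", patient_id = "p",
                              cohort_id = "c")),
    "duplicate")
})
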