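#' Functional marker panel
#'
#' The 14 functional markers whose per-population mean expression forms the
#' functional feature class: eight phospho-signaling readouts, four
#' intracellular proteins, and two surface markers.
#'
#' @return Character vector of length 14.
#' @export
functional_markers <- function() {
  c("pp38", "pSTAT1", "pSTAT3", "pCREB", "pNFkB", "pERK12", "pMAPKAPK2",
    "pS6", "VEGF", "GranzymeB", "Ki67", "ECadherin", "CD36", "CD44")
}

# Markers used by the deterministic gating rules. Ki67 and GranzymeB double
# as functional markers, as in a real IMC panel.
gating_markers <- function() {
  c("panCK", "Ki67", "CD45", "CD3", "CD4", "CD8", "FoxP3", "CD45RA", "CD20",
    "CD31", "aSMA", "collagen", "CD14", "CD68", "CD163", "CD206", "CD11b",
    "CD11c", "HLADR", "GranzymeB")
}

all_markers <- function() union(gating_markers(), functional_markers())

# Location parameters of the marker model on the arcsinh scale.
MARKER_MU_POS <- asinh(10)   # ~3.0, a clearly positive population
MARKER_MU_NEG <- asinh(0.2)  # ~0.2, background
MARKER_MU_BASE <- 1.0        # functional markers without a gate role
DNA_MU <- 3.0

#' Study-default cell populations
#'
#' The 15 populations of the default synthetic cohort with their expected
#' zonal densities (cells/mm^2 in stroma, front, core), mean cell area
#' (um^2) and mean eccentricity. Densities are calibrated qualitatively:
#' tumor populations concentrate in front/core, immune and structural
#' populations in stroma/front, CD8 T cells infiltrate the core.
#'
#' @return A data.frame with one row per population.
#' @export
default_populations <- function() {
  df <- read.csv(text = "
name,density_stroma,density_front,density_core,size_mean,eccentricity_mean
tumor_prolif,5,900,400,120,0.55
tumor_nonprolif,5,700,900,130,0.55
cd4_treg,120,150,10,55,0.6
cd4_naive,80,60,5,50,0.6
cd4_memory,250,200,10,60,0.6
cd8_t,200,250,120,55,0.6
b_cell,150,60,5,50,0.55
vessel,180,80,10,100,0.8
fibroblast,400,150,10,150,0.9
m1_mac,90,80,15,90,0.65
m2_mac,120,100,15,95,0.65
monocyte,100,60,8,70,0.6
granulocyte,80,70,10,60,0.6
dendritic,60,40,5,80,0.7
mdsc,120,30,3,70,0.6
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

# Binary gate profile: which gating markers each population expresses.
population_profiles <- function() {
  pops <- default_populations()$name
  gm <- gating_markers()
  P <- matrix(0L, length(pops), length(gm), dimnames = list(pops, gm))
  pos <- list(
    tumor_prolif    = c("panCK", "Ki67"),
    tumor_nonprolif = c("panCK"),
    cd4_treg        = c("CD45", "CD3", "CD4", "FoxP3"),
    cd4_naive       = c("CD45", "CD3", "CD4", "CD45RA"),
    cd4_memory      = c("CD45", "CD3", "CD4"),
    cd8_t           = c("CD45", "CD3", "CD8"),
    b_cell          = c("CD45", "CD20"),
    vessel          = c("CD31", "aSMA"),
    fibroblast      = c("collagen"),
    m1_mac          = c("CD45", "CD14", "CD68", "CD11b", "HLADR"),
    m2_mac          = c("CD45", "CD14", "CD68", "CD163", "CD206"),
    monocyte        = c("CD45", "CD14", "CD11b", "HLADR"),
    granulocyte     = c("CD45", "CD11b", "GranzymeB"),
    dendritic       = c("CD45", "CD11c", "HLADR"),
    mdsc            = c("CD45", "CD14", "CD11b")
  )
  for (p in names(pos)) P[p, pos[[p]]] <- 1L
  P
}

# Population x marker location matrix on the arcsinh scale.
default_marker_mu <- function() {
  prof <- population_profiles()
  mks <- all_markers()
  mu <- matrix(MARKER_MU_BASE, nrow(prof), length(mks),
               dimnames = list(rownames(prof), mks))
  gm <- colnames(prof)
  mu[, gm] <- ifelse(prof == 1L, MARKER_MU_POS, MARKER_MU_NEG)
  mu
}

#' Effect specification for planted grade differences
#'
#' Describes a single feature-level difference planted between the two grade
#' classes of a synthetic cohort: the named per-ROI feature is shifted in
#' the higher-grade class by `effect_size` standard deviations of that
#' feature (standardized mean difference).
#'
#' @param feature_class One of `density`, `function`, `metavariable`,
#'   `neighborhood`.
#' @param zone One of `stroma`, `front`, `core`.
#' @param population Population name.
#' @param marker Functional marker name (for `function` effects) or metric
#'   name (`size`, `eccentricity`, `border_dist`) for `metavariable`
#'   effects.
#' @param effect_size Standardized mean shift (may be negative).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(feature_class, zone, population, marker = NULL,
                        effect_size = 1) {
  classes <- c("density", "function", "metavariable", "neighborhood")
  if (!feature_class %in% classes)
    stopf("feature_class must be one of: %s", paste(classes, collapse = ", "))
  if (!zone %in% ZONES)
    stopf("zone must be one of: %s", paste(ZONES, collapse = ", "))
  structure(list(feature_class = feature_class, zone = zone,
                 population = population, marker = marker,
                 effect_size = effect_size),
            class = "effect_spec")
}

default_grade_effects <- function() {
  list(
    effect_spec("density", "front", "tumor_prolif", effect_size = 1.0),
    effect_spec("density", "core", "tumor_nonprolif", effect_size = 1.0),
    effect_spec("density", "stroma", "cd4_memory", effect_size = -1.0),
    effect_spec("function", "front", "granulocyte", "pMAPKAPK2", -1.0),
    effect_spec("metavariable", "stroma", "cd4_memory", "size", -1.0),
    effect_spec("metavariable", "front", "fibroblast", "border_dist", -1.0)
  )
}

#' Synthetic cohort configuration
#'
#' All knobs of the synthetic IMC cohort generator. Defaults emulate the
#' study conditions: 24 patients per cohort, 3 ROIs per patient, 1000 x 500
#' um ROIs at 1 um/pixel (500,000 pixels), widely varying tumor-covered
#' fraction, 15 populations with zone-dependent densities, and 14
#' functional markers.
#'
#' Density variation is lognormal with total log-scale SD `density_sigma`,
#' split between a patient-shared factor and an ROI factor so that the
#' correlation of log-densities between ROIs of one patient equals
#' `intrapatient_corr`. Functional marker values vary between ROIs with
#' log-scale SD `functional_tau` and between cells with SD
#' `functional_sigma` (arcsinh scale); gating markers carry cell-level noise
#' `lineage_sigma`.
#'
#' @param n_patients Patients per cohort.
#' @param rois_per_patient ROIs per patient (>= 1).
#' @param roi_shape `c(height, width)` in pixels.
#' @param pixel_size um per pixel.
#' @param tumor_fraction_range Interval in `[0,1]` from which each ROI's
#'   target tumor-covered fraction is drawn uniformly.
#' @param populations Population table as [default_populations()].
#' @param marker_mu Population x marker location matrix (arcsinh scale).
#' @param grade_effects List of [effect_spec()] planted in the higher class.
#' @param intrapatient_corr Correlation in `[0,1]` of patient-level density
#'   factors between ROIs of one patient.
#' @param density_sigma Total lognormal log-SD of per-ROI density factors.
#' @param functional_tau Between-ROI SD of functional marker levels.
#' @param functional_sigma Between-cell SD of functional marker levels.
#' @param lineage_sigma Between-cell SD of gating marker levels.
#' @param dna_sigma Between-cell SD of DNA intercalator signals.
#' @param cohort_id Cohort label stamped on every cell.
#' @param render_masks If `TRUE`, rasterize cells into label masks (ellipse
#'   rendering with overlap resolution) and recompute per-cell geometry from
#'   the masks; if `FALSE` (default) cells are points with parametric
#'   geometry attributes.
#' @param keep_masks Keep tumor (and label) masks in the returned object.
#' @param seed Integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 24, rois_per_patient = 3,
                          roi_shape = c(500, 1000), pixel_size = 1,
                          tumor_fraction_range = c(0.1, 0.8),
                          populations = default_populations(),
                          marker_mu = default_marker_mu(),
                          grade_effects = default_grade_effects(),
                          intrapatient_corr = 0.6,
                          density_sigma = 0.3,
                          functional_tau = 0.25,
                          functional_sigma = 0.5,
                          lineage_sigma = 0.35,
                          dna_sigma = 0.3,
                          cohort_id = "UOP",
                          render_masks = FALSE,
                          keep_masks = FALSE,
                          seed = 1L) {
  if (any(tumor_fraction_range < 0) || any(tumor_fraction_range > 1))
    stopf("tumor_fraction_range must lie within [0, 1]")
  if (rois_per_patient < 1) stopf("rois_per_patient must be >= 1")
  if (intrapatient_corr < 0 || intrapatient_corr > 1)
    stopf("intrapatient_corr must lie within [0, 1]")
  stopifnot(nrow(populations) >= 1, all(populations$size_mean > 0),
            all(populations[, c("density_stroma", "density_front",
                                "density_core")] >= 0))
  structure(list(n_patients = n_patients, rois_per_patient = rois_per_patient,
                 roi_shape = roi_shape, pixel_size = pixel_size,
                 tumor_fraction_range = tumor_fraction_range,
                 populations = populations, marker_mu = marker_mu,
                 grade_effects = grade_effects,
                 intrapatient_corr = intrapatient_corr,
                 density_sigma = density_sigma,
                 functional_tau = functional_tau,
                 functional_sigma = functional_sigma,
                 lineage_sigma = lineage_sigma, dna_sigma = dna_sigma,
                 cohort_id = cohort_id, render_masks = render_masks,
                 keep_masks = keep_masks, seed = as.integer(seed)),
            class = "cohort_config")
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  hw <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], hw), x, rep(x[n], hw))
    as.numeric(stats::filter(xp, k, sides = 2))[(hw + 1):(hw + n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

# Bilinear upscale of a matrix to (nr, nc).
bilinear_upscale <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- seq(1, sr, length.out = nr)
  ci <- seq(1, sc, length.out = nc)
  r0 <- pmin(floor(ri), sr - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1); c1 <- c0 + 1; fc <- ci - c0
  if (sr == 1) { r0 <- r1 <- rep(1, nr); fr <- rep(0, nr) }
  if (sc == 1) { c0 <- c1 <- rep(1, nc); fc <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc)
  d <- m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  e <- m[r1, c1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

#' Generate a synthetic binary tumor mask
#'
#' Thresholds a smoothed Gaussian random field at the order statistic
#' matching the target tumor-covered fraction, producing smooth blobs with
#' both convex and concave border stretches. The achieved fraction is exact
#' to pixel resolution; targets 0 and 1 give the empty and full mask
#' exactly.
#'
#' @param roi_shape `c(height, width)` in pixels.
#' @param target_fraction Desired tumor-covered fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param smoothness Correlation length of the field in pixels (controls
#'   blob scale).
#' @return Logical matrix (TRUE = tumor).
#' @export
generate_tumor_mask <- function(roi_shape, target_fraction, seed,
                                smoothness = 40) {
  if (!is.numeric(target_fraction) || target_fraction < 0 ||
      target_fraction > 1)
    stopf("target_fraction must lie within [0, 1]")
  nr <- roi_shape[1]; nc <- roi_shape[2]
  if (target_fraction == 0) return(matrix(FALSE, nr, nc))
  if (target_fraction == 1) return(matrix(TRUE, nr, nc))
  with_seed(seed, {
    fct <- 4
    cr <- max(8L, as.integer(ceiling(nr / fct)))
    cc <- max(8L, as.integer(ceiling(nc / fct)))
    field <- matrix(rnorm(cr * cc), cr, cc)
    field <- gaussian_blur(field, sigma = max(1, smoothness / fct))
    field <- bilinear_upscale(field, nr, nc)
    n_fg <- round(target_fraction * nr * nc)
    ord <- order(field, decreasing = TRUE)
    mask <- matrix(FALSE, nr, nc)
    mask[ord[seq_len(n_fg)]] <- TRUE
    mask
  })
}

# Draw per-cell attributes and marker intensities for one population in one
# ROI. `n` cells at pixel indices `idx` (linear) of a (nr x nc) grid.
draw_cells <- function(n, idx, nr, pop_row, mu_row, config, roi_fun_shift) {
  row_px <- ((idx - 1) %% nr) + 1
  col_px <- ((idx - 1) %/% nr) + 1
  x <- (col_px - 0.5 + runif(n, -0.4, 0.4)) * config$pixel_size
  y <- (row_px - 0.5 + runif(n, -0.4, 0.4)) * config$pixel_size
  area <- rlnorm(n, log(pop_row$size_mean) - 0.15^2 / 2, 0.15)
  em <- min(max(pop_row$eccentricity_mean, 0.01), 0.98)
  ecc <- stats::rbeta(n, em * 20, (1 - em) * 20)
  mks <- colnames(config$marker_mu)
  gm <- gating_markers()
  tmat <- matrix(rep(mu_row, each = n), nrow = n,
                 dimnames = list(NULL, mks))
  # between-ROI functional wobble (shared by all cells of the population)
  fm <- functional_markers()
  tmat[, fm] <- tmat[, fm] + rep(roi_fun_shift, each = n)
  sds <- ifelse(mks %in% fm, config$functional_sigma, config$lineage_sigma)
  # gate markers keep the tighter lineage noise even when also functional
  sds[mks %in% gm] <- config$lineage_sigma
  tmat <- tmat + matrix(rnorm(n * length(mks)), n) %*% diag(sds)
  raw <- sinh(pmax(tmat, 0))
  colnames(raw) <- paste0("raw_", mks)
  data.frame(x = x, y = y, row_px = row_px, col_px = col_px, area = area,
             eccentricity = ecc,
             dna1 = sinh(rnorm(n, DNA_MU, config$dna_sigma)),
             dna2 = sinh(rnorm(n, DNA_MU, config$dna_sigma)),
             as.data.frame(raw))
}

#' Generate a synthetic IMC cohort
#'
#' Generates tumor masks, places cells by an inhomogeneous Poisson process
#' whose per-zone intensity follows the population table (scaled by
#' patient- and ROI-level lognormal factors), draws marker intensities from
#' the population marker model, assigns zones from the exact signed border
#' distance, and plants the configured grade effects in the higher-grade
#' class. Patients are assigned balanced `low`/`high` grade labels.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: a list with `cells` (one
#'   data.frame for the whole cohort), `zones` (per-ROI zone areas and
#'   tumor fraction), `meta` (per-ROI patient/cohort/grade), `masks`
#'   (optional, per-ROI list of `tumor_mask`/`label_mask`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  pops <- config$populations
  nr <- config$roi_shape[1]; nc <- config$roi_shape[2]
  rho <- config$intrapatient_corr
  sig_p <- config$density_sigma * sqrt(rho)
  sig_r <- config$density_sigma * sqrt(1 - rho)
  n_roi_total <- config$n_patients * config$rois_per_patient

  meta <- data.frame(
    roi_id = sprintf("%s_P%02d_R%d", config$cohort_id,
                     rep(seq_len(config$n_patients),
                         each = config$rois_per_patient),
                     rep(seq_len(config$rois_per_patient),
                         config$n_patients)),
    patient_id = sprintf("%s_P%02d", config$cohort_id,
                         rep(seq_len(config$n_patients),
                             each = config$rois_per_patient)),
    cohort_id = config$cohort_id,
    grade = rep(ifelse(seq_len(config$n_patients) %% 2 == 1, "low", "high"),
                each = config$rois_per_patient),
    stringsAsFactors = FALSE)

  patient_factor <- with_seed(derive_seed(config$seed, 0), {
    exp(rnorm(config$n_patients, -sig_p^2 / 2, sig_p))
  })

  zcfg <- zone_config(pixel_size = config$pixel_size)
  cells_list <- vector("list", n_roi_total)
  zones_list <- vector("list", n_roi_total)
  masks <- if (config$keep_masks) vector("list", n_roi_total) else NULL

  for (r in seq_len(n_roi_total)) {
    seed_r <- derive_seed(config$seed, r)
    pat_idx <- (r - 1) %/% config$rois_per_patient + 1
    roi_cells <- with_seed(seed_r, {
      target <- runif(1, config$tumor_fraction_range[1],
                      config$tumor_fraction_range[2])
      mask <- generate_tumor_mask(c(nr, nc), target,
                                  seed = derive_seed(seed_r, 1))
      dist <- signed_border_distance(mask, zcfg)
      zm <- zone_areas(mask, zcfg, dist = dist)
      zone_px <- list(
        stroma = which(dist$distance > zcfg$band_halfwidth),
        front = which(abs(dist$distance) <= zcfg$band_halfwidth),
        core = which(dist$distance < -zcfg$band_halfwidth))
      f_roi <- exp(rnorm(1, -sig_r^2 / 2, sig_r))
      f_tot <- patient_factor[pat_idx] * f_roi
      roi_fun_shift <- matrix(
        rnorm(nrow(pops) * length(functional_markers()), 0,
              config$functional_tau),
        nrow(pops), dimnames = list(pops$name, functional_markers()))
      out <- vector("list", nrow(pops) * 3)
      k <- 0
      for (p in seq_len(nrow(pops))) {
        dens <- c(pops$density_stroma[p], pops$density_front[p],
                  pops$density_core[p])
        for (zi in 1:3) {
          zone <- ZONES[zi]
          npx <- length(zone_px[[zone]])
          if (npx == 0 || dens[zi] <= 0) next
          area_mm2 <- npx * (config$pixel_size^2) / 1e6
          n_cells <- rpois(1, dens[zi] * f_tot * area_mm2)
          if (n_cells == 0) next
          idx <- sample(zone_px[[zone]], n_cells, replace = TRUE)
          d <- draw_cells(n_cells, idx, nr, pops[p, ],
                          config$marker_mu[pops$name[p], ], config,
                          roi_fun_shift[pops$name[p], ])
          d$population <- pops$name[p]
          d$dist_border <- dist$distance[idx]
          d$zone <- zone
          k <- k + 1
          out[[k]] <- d
        }
      }
      cells <- if (k > 0) do.call(rbind, out[seq_len(k)]) else NULL
      list(cells = cells, zm = zm, mask = mask, dist = dist)
    })
    cells <- roi_cells$cells
    if (!is.null(cells)) {
      cells$roi_id <- meta$roi_id[r]
      cells$patient_id <- meta$patient_id[r]
      cells$cohort_id <- meta$cohort_id[r]
      cells$grade <- meta$grade[r]
    }
    cells_list[[r]] <- cells
    zm <- roi_cells$zm
    zones_list[[r]] <- data.frame(
      roi_id = meta$roi_id[r], area_roi = zm$area_roi,
      area_tumor = zm$area_tumor, area_stroma = zm$zone_areas["stroma"],
      area_front = zm$zone_areas["front"], area_core = zm$zone_areas["core"],
      tumor_fraction = tumor_covered_fraction(zm),
      stringsAsFactors = FALSE, row.names = NULL)
    if (config$keep_masks)
      masks[[r]] <- list(tumor_mask = roi_cells$mask, label_mask = NULL)
  }

  cells <- do.call(rbind, cells_list[!vapply(cells_list, is.null, TRUE)])
  rownames(cells) <- NULL
  cells$cell_id <- seq_len(nrow(cells))

  if (length(config$grade_effects) > 0)
    cells <- plant_effects(cells, config$grade_effects,
                           grade = "high",
                           seed = derive_seed(config$seed, 999999L))

  if (config$render_masks) {
    lab_masks <- vector("list", n_roi_total)
    new_cells <- vector("list", n_roi_total)
    for (r in seq_len(n_roi_total)) {
      rc <- cells[cells$roi_id == meta$roi_id[r], , drop = FALSE]
      lm <- rasterize_cells(rc, c(nr, nc), pixel_size = config$pixel_size,
                            seed = derive_seed(config$seed, 500000L + r),
                            roi_id = meta$roi_id[r])
      lab_masks[[r]] <- lm
      new_cells[[r]] <- rc
    }
    cells <- do.call(rbind, new_cells)
    rownames(cells) <- NULL
    if (config$keep_masks)
      for (r in seq_len(n_roi_total)) masks[[r]]$label_mask <- lab_masks[[r]]
  }

  structure(list(cells = cells,
                 zones = do.call(rbind, zones_list),
                 meta = meta,
                 masks = masks,
                 config = config),
            class = "synthetic_cohort")
}

# Pixel set of an ellipse (center cx,cy in um; semi-axes a,b in um; angle
# theta) on an nr x nc grid at `pixel_size` um/px. Returns linear indices.
ellipse_pixels <- function(cx, cy, a, b, theta, nr, nc, pixel_size = 1) {
  r_c <- cy / pixel_size + 0.5; c_c <- cx / pixel_size + 0.5
  ext <- max(a, b) / pixel_size
  r0 <- max(1L, floor(r_c - ext)); r1 <- min(nr, ceiling(r_c + ext))
  c0 <- max(1L, floor(c_c - ext)); c1 <- min(nc, ceiling(c_c + ext))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- (rr - r_c) * pixel_size
  dx <- (cc - c_c) * pixel_size
  DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
  DY <- matrix(dy, length(rr), length(cc))
  u <- DX * cos(theta) + DY * sin(theta)
  v <- -DX * sin(theta) + DY * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  which_in <- which(inside, arr.ind = TRUE)
  if (nrow(which_in) == 0) {
    # guarantee at least the center pixel
    rc <- min(max(round(r_c), 1L), nr); ccx <- min(max(round(c_c), 1L), nc)
    return((ccx - 1L) * nr + rc)
  }
  (cc[which_in[, 2]] - 1L) * nr + rr[which_in[, 1]]
}

# Rasterize cells of one ROI into a label mask. Overlaps are resolved by
# re-sampling the position locally (up to 100 retries) and then shrinking
# the ellipse; a cell that still cannot be placed raises a generation error
# naming the ROI.
rasterize_cells <- function(cells, roi_shape, pixel_size = 1, seed = 1,
                            roi_id = "?") {
  nr <- roi_shape[1]; nc <- roi_shape[2]
  lab <- matrix(0L, nr, nc)
  with_seed(seed, {
    for (i in seq_len(nrow(cells))) {
      a0 <- sqrt(cells$area[i] / pi / sqrt(1 - cells$eccentricity[i]^2))
      b0 <- a0 * sqrt(1 - cells$eccentricity[i]^2)
      theta <- runif(1, 0, pi)
      placed <- FALSE
      a <- a0; b <- b0
      cx <- cells$x[i]; cy <- cells$y[i]
      for (shrink in 0:8) {
        for (try in 0:100) {
          px <- ellipse_pixels(cx, cy, a, b, theta, nr, nc, pixel_size)
          if (length(px) > 0 && all(lab[px] == 0L)) {
            lab[px] <- cells$cell_id[i]
            placed <- TRUE
            break
          }
          # local jitter retry
          cx <- cells$x[i] + runif(1, -5, 5)
          cy <- cells$y[i] + runif(1, -5, 5)
        }
        if (placed) break
        a <- a * 0.8; b <- b * 0.8
        if (a < pixel_size / 2) break
      }
      if (!placed)
        stopf("cell placement failed in ROI %s (cell %d)", roi_id,
              cells$cell_id[i])
    }
  })
  lab
}

#' Plant grade-associated effects into a cell table
#'
#' Shifts per-ROI features of the `grade` class (the higher-grade class) by
#' `effect_size` standard deviations of the feature, computed across all
#' ROIs of the table before shifting. Density effects rescale the cell count
#' of the population/zone (binomial thinning for negative shifts,
#' duplication with positional jitter for positive ones); `function` and
#' `metavariable` effects shift the named quantity of the affected cells.
#' An empty effect list or zero effect sizes return the input unchanged.
#'
#' @param cells Cohort cell table with `roi_id`, `grade`, `population`,
#'   `zone` columns.
#' @param effects List of [effect_spec()].
#' @param grade Label of the class receiving the shift.
#' @param seed Integer seed (used by density resampling).
#' @return The modified cell table.
#' @export
plant_effects <- function(cells, effects, grade = "high", seed = 1) {
  if (length(effects) == 0) return(cells)
  pops <- unique(cells$population)
  for (k in seq_along(effects)) {
    ef <- effects[[k]]
    if (!ef$population %in% pops)
      stopf("effect %d references unknown population '%s'", k, ef$population)
    if (ef$feature_class == "function" &&
        !paste0("raw_", ef$marker) %in% names(cells))
      stopf("effect %d references unknown marker '%s'", k, ef$marker)
    if (ef$feature_class == "neighborhood")
      stopf("planting neighborhood effects is not supported")
    if (ef$effect_size == 0) next
    sel <- cells$population == ef$population & cells$zone == ef$zone
    hi <- cells$grade == grade
    if (ef$feature_class == "density") {
      counts <- table(factor(cells$roi_id[sel],
                             levels = unique(cells$roi_id)))
      m <- mean(counts); s <- sd(counts)
      if (m == 0) next
      scale <- max(0.05, 1 + ef$effect_size * s / m)
      idx <- which(sel & hi)
      if (scale < 1) {
        drop <- idx[runif2(length(idx), seed, k * 7 + 1) >= scale]
        if (length(drop) > 0) cells <- cells[-drop, , drop = FALSE]
      } else if (scale > 1) {
        extra <- scale - 1
        n_new <- floor(extra * length(idx)) +
          (runif2(1, seed, k * 7 + 2) < (extra * length(idx)) %% 1)
        if (n_new > 0) {
          pick <- idx[ceiling(runif2(n_new, seed, k * 7 + 3) * length(idx))]
          dup <- cells[pick, , drop = FALSE]
          jit <- matrix(runif2(2 * n_new, seed, k * 7 + 4) * 6 - 3,
                        ncol = 2)
          dup$x <- pmax(0, dup$x + jit[, 1])
          dup$y <- pmax(0, dup$y + jit[, 2])
          dup$cell_id <- max(cells$cell_id) + seq_len(n_new)
          cells <- rbind(cells, dup)
        }
      }
    } else if (ef$feature_class == "function") {
      col <- paste0("raw_", ef$marker)
      tvals <- asinh(cells[[col]][sel])
      roi_means <- tapply(tvals, cells$roi_id[sel], mean)
      s <- sd(roi_means, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      shift_idx <- which(sel & hi)
      cells[[col]][shift_idx] <-
        sinh(pmax(asinh(cells[[col]][shift_idx]) + ef$effect_size * s, 0))
    } else { # metavariable
      col <- switch(ef$marker, size = "area",
                    eccentricity = "eccentricity",
                    border_dist = "dist_border",
                    stopf("unknown metavariable metric '%s'", ef$marker))
      msel <- if (ef$marker == "border_dist") sel & cells$zone == "front"
              else sel
      vals <- cells[[col]][msel]
      roi_means <- tapply(vals, cells$roi_id[msel], mean)
      s <- sd(roi_means, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      shift_idx <- which(msel & hi)
      newv <- cells[[col]][shift_idx] + ef$effect_size * s
      if (col == "area") newv <- pmax(newv, 1)
      if (col == "eccentricity") newv <- pmin(pmax(newv, 0), 0.99)
      cells[[col]][shift_idx] <- newv
    }
  }
  rownames(cells) <- NULL
  cells
}

# Deterministic uniforms from (seed, stream) without touching the caller's
# RNG state.
runif2 <- function(n, seed, stream) {
  with_seed(derive_seed(seed, stream), runif(n))
}

#' Simulate a model-ready feature matrix with planted effects
#'
#' Direct feature-level simulator for testing the modeling stage: each
#' feature has unit variance, split between a patient random effect
#' (variance `intrapatient_corr`) and ROI noise; informative features are
#' shifted by `effect_size` in the higher-grade class. Features are
#' assigned round-robin to the four feature classes so the stability
#' selection and late-fusion machinery is exercised per class.
#'
#' @param n_patients,rois_per_patient Cohort layout (grades balanced across
#'   patients).
#' @param n_features Total number of features.
#' @param n_informative Number of features carrying the planted effect.
#' @param effect_size Standardized mean difference of informative features.
#' @param intrapatient_corr Fraction of feature variance due to the patient.
#' @param seed Integer seed.
#' @return A [feature_matrix] whose `col_info$informative` flags the
#'   planted features.
#' @export
simulate_feature_matrix <- function(n_patients = 24, rois_per_patient = 3,
                                    n_features = 100, n_informative = 10,
                                    effect_size = 1.2,
                                    intrapatient_corr = 0.5, seed = 1) {
  n <- n_patients * rois_per_patient
  classes <- c("density", "function", "metavariable", "neighborhood")
  with_seed(seed, {
    patient <- rep(seq_len(n_patients), each = rois_per_patient)
    grade <- rep(ifelse(seq_len(n_patients) %% 2 == 1, "low", "high"),
                 each = rois_per_patient)
    rho <- intrapatient_corr
    U <- matrix(rnorm(n_patients * n_features), n_patients)
    E <- matrix(rnorm(n * n_features), n)
    X <- sqrt(rho) * U[patient, , drop = FALSE] + sqrt(1 - rho) * E
    informative <- seq_len(n_informative)
    X[grade == "high", informative] <-
      X[grade == "high", informative] + effect_size
    fclass <- rep(classes, length.out = n_features)
    cn <- sprintf("%s:sim:f%03d", fclass, seq_len(n_features))
    colnames(X) <- cn
    row_info <- data.frame(
      roi_id = sprintf("SIM_P%02d_R%d", patient,
                       rep(seq_len(rois_per_patient), n_patients)),
      patient_id = sprintf("SIM_P%02d", patient),
      cohort_id = "SIM", grade = grade, stringsAsFactors = FALSE)
    rownames(X) <- row_info$roi_id
    col_info <- data.frame(name = cn, feature_class = fclass, zone = "sim",
                           population = "sim",
                           informative = seq_len(n_features) %in% informative,
                           stringsAsFactors = FALSE)
    feature_matrix(X, col_info, row_info)
  })
}
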