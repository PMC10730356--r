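#' Neighborhood configuration
#'
#' A cell's neighbors are its up-to-`k` nearest cells whose distance does
#' not exceed `max_dist`. The default distance is border-to-border: the
#' minimum Euclidean distance between the two cells' boundary pixel sets
#' when boundaries are available, and the equivalent-circle surrogate
#' (centroid distance minus both radii, floored at 0) for point-mode
#' synthetic cells. `centroid` mode is provided for speed.
#'
#' @param k Maximum number of neighbors.
#' @param max_dist Distance cutoff in micrometres.
#' @param distance_mode `"border"` (default) or `"centroid"`.
#' @return Object of class `neighbor_config`.
#' @export
neighbor_config <- function(k = 5, max_dist = 20,
                            distance_mode = c("border", "centroid")) {
  distance_mode <- match.arg(distance_mode)
  if (k < 1) stopf("k must be >= 1")
  if (max_dist <= 0) stopf("max_dist must be > 0")
  structure(list(k = k, max_dist = max_dist, distance_mode = distance_mode),
            class = "neighbor_config")
}

#' Feature matrix container
#'
#' Samples (ROIs) by features, with per-column annotations (feature class,
#' zone, population, ...) and per-row annotations (patient, cohort, grade).
#'
#' @param x Numeric matrix, rows = ROIs.
#' @param col_info Data.frame with at least `name` and `feature_class`,
#'   one row per column of `x`.
#' @param row_info Data.frame with at least `roi_id`, `patient_id`,
#'   `cohort_id`, one row per row of `x`.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, col_info, row_info) {
  stopifnot(ncol(x) == nrow(col_info), nrow(x) == nrow(row_info))
  if (anyDuplicated(col_info$name))
    stopf("duplicate feature names in feature matrix")
  colnames(x) <- col_info$name
  structure(list(x = x, col_info = col_info, row_info = row_info),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d ROIs x %d features\n",
              nrow(x$x), ncol(x$x)))
  print(table(x$col_info$feature_class))
  invisible(x)
}

#' Zonal cell-population densities
#'
#' Count of each population in each zone of each ROI divided by the zone
#' area (cells/mm^2). Zones with zero area yield missing densities, not
#' zeros, so absence of tissue is never conflated with absence of cells.
#'
#' @param cells Cell table with `roi_id`, `population`, `zone`.
#' @param zones Per-ROI zone areas (`roi_id`, `area_stroma`, `area_front`,
#'   `area_core`).
#' @param populations Population levels (defaults to those present).
#' @return Long data.frame: `roi_id`, `population`, `zone`, `count`,
#'   `area`, `density`.
#' @export
zonal_density <- function(cells, zones, populations = NULL) {
  populations <- populations %||% sort(unique(cells$population))
  roi_ids <- zones$roi_id
  if (length(roi_ids) == 0)
    return(data.frame(roi_id = character(0), zone = character(0),
                      population = character(0), count = integer(0),
                      area = numeric(0), density = numeric(0)))
  counts <- as.data.frame(table(
    roi_id = factor(cells$roi_id, levels = roi_ids),
    population = factor(cells$population, levels = populations),
    zone = factor(cells$zone, levels = ZONES)), responseName = "count")
  area_long <- data.frame(
    roi_id = rep(zones$roi_id, times = 3),
    zone = rep(ZONES, each = nrow(zones)),
    area = c(zones$area_stroma, zones$area_front, zones$area_core))
  out <- merge(counts, area_long, by = c("roi_id", "zone"), sort = FALSE)
  out$density <- ifelse(out$area > 0, out$count / out$area, NA_real_)
  out$roi_id <- as.character(out$roi_id)
  out$population <- as.character(out$population)
  out$zone <- as.character(out$zone)
  out[order(match(out$roi_id, roi_ids), match(out$zone, ZONES),
            match(out$population, populations)), ]
}

#' Retained (population, zone) combinations
#'
#' A combination is retained when its median zonal density across ROIs is
#' positive; combinations with median zero are excluded from the function,
#' metavariable and neighborhood classes of that zone (never from the
#' density class). Densities undefined because of zero zone area are
#' ignored in the median; a combination undefined everywhere is not
#' retained.
#'
#' @param density_long Output of [zonal_density()] for the whole cohort.
#' @return Data.frame `population`, `zone`, `median_density`, `retained`.
#' @export
retained_combos <- function(density_long) {
  if (nrow(density_long) == 0)
    return(data.frame(population = character(0), zone = character(0),
                      median_density = numeric(0), retained = logical(0)))
  agg <- aggregate(density ~ population + zone, data = density_long,
                   FUN = function(v) median(v, na.rm = TRUE),
                   na.action = stats::na.pass)
  names(agg)[3] <- "median_density"
  agg$retained <- !is.na(agg$median_density) & agg$median_density > 0
  agg
}

# mean of `value` per (roi, population, zone), restricted to retained
# combos; returns a wide ROI x feature matrix given a naming function.
combo_means <- function(cells, value, roi_ids, combos, prefix, suffix = NULL) {
  keep_combo <- paste(combos$population, combos$zone, sep = "|")[combos$retained]
  key <- paste(cells$population, cells$zone, sep = "|")
  sel <- key %in% keep_combo
  cn_combo <- combos[combos$retained, c("population", "zone")]
  cn_combo <- cn_combo[order(match(cn_combo$zone, ZONES), cn_combo$population), ]
  feat_names <- if (nrow(cn_combo) == 0) character(0) else
    paste0(prefix, ":", cn_combo$zone, ":", cn_combo$population,
           if (!is.null(suffix)) paste0(":", suffix) else "")
  m <- matrix(NA_real_, length(roi_ids), nrow(cn_combo),
              dimnames = list(roi_ids, feat_names))
  if (any(sel)) {
    g_roi <- factor(cells$roi_id[sel], levels = roi_ids)
    g_combo <- factor(paste(cells$population, cells$zone, sep = "|")[sel],
                      levels = paste(cn_combo$population, cn_combo$zone,
                                     sep = "|"))
    mm <- tapply(value[sel], list(g_roi, g_combo), mean)
    m[, ] <- mm
  }
  list(x = m, combos = cn_combo)
}

#' Functional features: mean marker expression per population and zone
#'
#' Arithmetic mean of the arcsinh-transformed marker intensity over the
#' cells of each retained (population, zone) combination, per ROI. ROIs
#' without such cells get missing values.
#'
#' @param cells Cell table with `raw_<marker>` columns.
#' @param combos [retained_combos()] output.
#' @param roi_ids ROI ordering for the rows.
#' @param markers Functional marker names.
#' @param cofactor Arcsinh cofactor.
#' @return List `x` (matrix), `col_info`.
#' @export
functional_features <- function(cells, combos, roi_ids,
                                markers = functional_markers(),
                                cofactor = 1) {
  mats <- list(); infos <- list()
  for (mk in markers) {
    v <- arcsinh_transform(cells[[paste0("raw_", mk)]], cofactor)
    cm <- combo_means(cells, v, roi_ids, combos, "function", mk)
    mats[[mk]] <- cm$x
    nfc <- ncol(cm$x)
    infos[[mk]] <- data.frame(name = colnames(cm$x) %||% character(0),
                              feature_class = rep("function", nfc),
                              zone = cm$combos$zone,
                              population = cm$combos$population,
                              marker = rep(mk, nfc),
                              stringsAsFactors = FALSE)
  }
  # order: zone-major within marker blocks -> reorder to marker within combo
  x <- do.call(cbind, mats)
  ci <- do.call(rbind, infos)
  ord <- order(match(ci$zone, ZONES), ci$population,
               match(ci$marker, markers))
  list(x = x[, ord, drop = FALSE], col_info = ci[ord, ])
}

#' Spatial metavariables: mean size, eccentricity and border distance
#'
#' Mean cell area and mean eccentricity per retained (population, zone)
#' combination, plus the mean signed tumor-border distance per population
#' for the tumor-front zone only (border distance elsewhere is dominated by
#' the tumor-area geometry of the ROI, not cell behavior, and is therefore
#' not emitted).
#'
#' @inheritParams functional_features
#' @return List `x` (matrix), `col_info`.
#' @export
spatial_metavariables <- function(cells, combos, roi_ids) {
  sz <- combo_means(cells, cells$area, roi_ids, combos, "metavariable",
                    "size")
  ec <- combo_means(cells, cells$eccentricity, roi_ids, combos,
                    "metavariable", "eccentricity")
  front_combos <- combos
  front_combos$retained <- front_combos$retained & front_combos$zone == "front"
  dd <- combo_means(cells, cells$dist_border, roi_ids, front_combos,
                    "metavariable", "border_dist")
  x <- cbind(sz$x, ec$x, dd$x)
  meta_info <- function(cm, metric) {
    k <- ncol(cm$x)
    data.frame(name = colnames(cm$x) %||% character(0),
               feature_class = rep("metavariable", k),
               zone = cm$combos$zone, population = cm$combos$population,
               marker = rep(metric, k), stringsAsFactors = FALSE)
  }
  ci <- rbind(meta_info(sz, "size"), meta_info(ec, "eccentricity"),
              meta_info(dd, "border_dist"))
  ord <- order(match(ci$zone, ZONES), ci$population,
               match(ci$marker, c("size", "eccentricity", "border_dist")))
  list(x = x[, ord, drop = FALSE], col_info = ci[ord, ])
}

# Neighbor lists for the cells of one ROI: up to k nearest within max_dist.
# Returns list(center index -> integer vector of neighbor indices).
neighbor_lists <- function(cells, config, boundaries = NULL) {
  n <- nrow(cells)
  coords <- cbind(cells$x, cells$y)
  if (config$distance_mode == "centroid") {
    mode <- 0L; ext <- numeric(n); blist <- list()
  } else if (!is.null(boundaries)) {
    blist <- boundaries[as.character(cells$cell_id)]
    ext <- vapply(seq_len(n), function(i) {
      b <- blist[[i]]
      if (is.null(b) || nrow(b) == 0) return(0)
      max(sqrt((b[, 1] - cells$x[i])^2 + (b[, 2] - cells$y[i])^2))
    }, 1)
    mode <- 2L
  } else {
    ext <- sqrt(cells$area / pi)
    mode <- 1L; blist <- list()
  }
  edges <- neighbor_pairs_cpp(coords, config$max_dist, mode, ext,
                              if (mode == 2L) blist else list())
  nbr <- vector("list", n)
  if (nrow(edges) > 0) {
    all_i <- c(edges$i, edges$j)
    all_j <- c(edges$j, edges$i)
    all_d <- c(edges$dist, edges$dist)
    sp <- split(seq_along(all_i), all_i)
    for (ci in names(sp)) {
      rows <- sp[[ci]]
      ord <- rows[order(all_d[rows], all_j[rows])]
      nbr[[as.integer(ci)]] <- all_j[head(ord, config$k)]
    }
  }
  nbr
}

#' Neighborhood coefficients
#'
#' For each center cell, the coefficient vector is the proportion of its
#' neighbors (up to `k` nearest within `max_dist`) belonging to each
#' population; cells with no neighbor contribute nothing. The module output
#' is the mean coefficient over the center cells of each population within
#' each zone (the zone of the center cell), for retained center and partner
#' combinations of that zone.
#'
#' @param cells Cell table (one or more ROIs).
#' @param combos [retained_combos()] output.
#' @param roi_ids ROI ordering.
#' @param config A [neighbor_config()].
#' @param boundaries Optional named list (by `cell_id`) of boundary pixel
#'   coordinate matrices (micrometres) for exact border distances.
#' @param populations Partner population levels.
#' @return List `x` (matrix), `col_info`.
#' @export
neighborhood_coefficients <- function(cells, combos, roi_ids,
                                      config = neighbor_config(),
                                      boundaries = NULL,
                                      populations = NULL) {
  populations <- populations %||% sort(unique(cells$population))
  ret <- combos[combos$retained, , drop = FALSE]
  ret <- ret[order(match(ret$zone, ZONES), ret$population), ]
  feat <- do.call(rbind, lapply(seq_len(nrow(ret)), function(i) {
    partners <- ret$population[ret$zone == ret$zone[i]]
    data.frame(zone = ret$zone[i], center = ret$population[i],
               partner = partners, stringsAsFactors = FALSE)
  }))
  if (is.null(feat) || nrow(feat) == 0) {
    return(list(x = matrix(NA_real_, length(roi_ids), 0,
                           dimnames = list(roi_ids, NULL)),
                col_info = data.frame(name = character(0),
                                      feature_class = character(0),
                                      zone = character(0),
                                      population = character(0),
                                      partner = character(0))))
  }
  feat$name <- paste("neighborhood", feat$zone, feat$center, feat$partner,
                     sep = ":")
  x <- matrix(NA_real_, length(roi_ids), nrow(feat),
              dimnames = list(roi_ids, feat$name))
  acc <- matrix(0, nrow(feat), 2,
                dimnames = list(feat$name, c("sum", "n")))
  for (roi in roi_ids) {
    rc <- cells[cells$roi_id == roi, , drop = FALSE]
    if (nrow(rc) == 0) next
    nbr <- neighbor_lists(rc, config, boundaries)
    known <- rc$population %in% populations
    acc[, ] <- 0
    for (i in seq_len(nrow(rc))) {
      if (!known[i]) next
      nb <- nbr[[i]]
      if (is.null(nb) || length(nb) == 0) next
      nb <- nb[known[nb]]
      if (length(nb) == 0) next
      props <- tabulate(match(rc$population[nb], populations),
                        nbins = length(populations)) / length(nb)
      rows <- which(feat$zone == rc$zone[i] & feat$center == rc$population[i])
      if (length(rows) == 0) next
      pidx <- match(feat$partner[rows], populations)
      acc[rows, "sum"] <- acc[rows, "sum"] + props[pidx]
      acc[rows, "n"] <- acc[rows, "n"] + 1
    }
    has <- acc[, "n"] > 0
    x[roi, has] <- acc[has, "sum"] / acc[has, "n"]
  }
  list(x = x,
       col_info = data.frame(name = feat$name,
                             feature_class = "neighborhood",
                             zone = feat$zone, population = feat$center,
                             partner = feat$partner,
                             stringsAsFactors = FALSE))
}

#' Assemble the four-class feature matrix
#'
#' Builds zonal densities, functional features, spatial metavariables and
#' neighborhood coefficients for a cohort and binds them into one
#' [feature_matrix]. The density class always spans the full population x
#' zone grid; the other three classes span the retained combinations
#' (median zonal density > 0), all sharing the same retained set. Column
#' order is deterministic: class, then zone (stroma, front, core), then
#' population, then marker/metric/partner.
#'
#' @param cells Cohort cell table (after QC/typing; the `population` column
#'   is the cell type used for features).
#' @param zones Per-ROI zone area table.
#' @param meta Per-ROI metadata (`roi_id`, `patient_id`, `cohort_id`,
#'   `grade`, optional outcomes).
#' @param populations Population levels (defaults to the study's 15).
#' @param markers Functional markers.
#' @param nbr_config A [neighbor_config()].
#' @param boundaries Optional per-cell boundary coordinates (see
#'   [neighborhood_coefficients()]).
#' @param cofactor Arcsinh cofactor.
#' @return A [feature_matrix].
#' @export
assemble_feature_matrix <- function(cells, zones, meta,
                                    populations = default_populations()$name,
                                    markers = functional_markers(),
                                    nbr_config = neighbor_config(),
                                    boundaries = NULL, cofactor = 1) {
  roi_ids <- meta$roi_id
  dl <- zonal_density(cells, zones, populations)
  combos <- retained_combos(dl)

  # density class: full grid, zone-major then population
  dl$feature <- if (nrow(dl) > 0)
    paste("density", dl$zone, dl$population, sep = ":") else character(0)
  combo_grid <- expand.grid(population = populations, zone = ZONES,
                            stringsAsFactors = FALSE)
  combo_grid <- combo_grid[order(match(combo_grid$zone, ZONES),
                                 match(combo_grid$population, populations)), ]
  dens_names <- paste("density", combo_grid$zone, combo_grid$population,
                      sep = ":")
  dx <- matrix(NA_real_, length(roi_ids), length(dens_names),
               dimnames = list(roi_ids, dens_names))
  dx[cbind(match(dl$roi_id, roi_ids), match(dl$feature, dens_names))] <-
    dl$density
  dens_info <- data.frame(name = dens_names, feature_class = "density",
                          zone = combo_grid$zone,
                          population = combo_grid$population,
                          stringsAsFactors = FALSE)

  fn <- functional_features(cells, combos, roi_ids, markers, cofactor)
  mv <- spatial_metavariables(cells, combos, roi_ids)
  nb <- neighborhood_coefficients(cells, combos, roi_ids, nbr_config,
                                  boundaries, populations)

  pad <- function(ci) {
    for (col in c("marker", "partner"))
      if (!col %in% names(ci)) ci[[col]] <- rep(NA_character_, nrow(ci))
    ci[, c("name", "feature_class", "zone", "population", "marker",
           "partner")]
  }
  col_info <- rbind(pad(dens_info), pad(fn$col_info), pad(mv$col_info),
                    pad(nb$col_info))
  x <- cbind(dx, fn$x, mv$x, nb$x)
  rownames(col_info) <- NULL
  fm <- feature_matrix(x, col_info, meta)
  attr(fm, "combos") <- combos
  fm
}
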