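#' Arcsinh transform of marker intensities
#'
#' The variance-stabilizing transform standard in mass cytometry:
#' `asinh(x / cofactor)`. Strictly monotone; behaves like `x/cofactor` near
#' zero and like `log(2x/cofactor)` for large intensities.
#'
#' @param x Nonnegative intensities.
#' @param cofactor Positive scale divisor (default 1).
#' @return Transformed intensities.
#' @export
arcsinh_transform <- function(x, cofactor = 1) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stopf("cofactor must be a positive scalar")
  asinh(x / cofactor)
}

# Add t_<marker> columns for every raw_<marker> column.
add_transformed_markers <- function(cells, cofactor = 1) {
  raw_cols <- grep("^raw_", names(cells), value = TRUE)
  for (rc in raw_cols)
    cells[[sub("^raw_", "t_", rc)]] <- arcsinh_transform(cells[[rc]], cofactor)
  cells
}

#' Quality-control filter on segmented cells
#'
#' Removes segmented objects smaller than `min_area_px` pixels and cells
#' whose DNA intercalator signals (`dna1`, `dna2`, raw scale) fall outside
#' mean +/- `dna_sd` standard deviations; the DNA statistics are computed
#' per cohort on the pre-filter table. A cohort whose DNA signal has zero
#' spread (SD = 0) disables the DNA rule for that cohort with a warning.
#'
#' @param cells Cell table with `area` (um^2; at 1 um/pixel equal to pixel
#'   count), `dna1`, `dna2`, and `cohort_id` columns.
#' @param min_area_px Minimum object size in pixels.
#' @param dna_sd Width of the DNA acceptance band in SD units.
#' @param pixel_size um per pixel, to convert `area` to pixel counts.
#' @param dna_stats Optional frozen DNA statistics (the `dna_stats`
#'   attribute of a previous [qc_filter()] call); when supplied the DNA
#'   band is not re-estimated, making the filter idempotent.
#' @return The filtered table; attribute `qc_removed` reports counts removed
#'   per rule, attribute `dna_stats` the per-cohort mean/SD used.
#' @export
qc_filter <- function(cells, min_area_px = 10, dna_sd = 2, pixel_size = 1,
                      dna_stats = NULL) {
  if (nrow(cells) == 0) {
    warnf("qc_filter: empty cell table")
    attr(cells, "qc_removed") <- c(area = 0L, dna = 0L)
    return(cells)
  }
  if (!all(c("dna1", "dna2") %in% names(cells)))
    stopf("qc_filter requires dna1/dna2 columns")
  area_px <- cells$area / (pixel_size^2)
  small <- area_px < min_area_px
  dna_out <- rep(FALSE, nrow(cells))
  stats_used <- list()
  for (co in unique(cells$cohort_id)) {
    in_co <- cells$cohort_id == co
    for (col in c("dna1", "dna2")) {
      v <- cells[[col]][in_co]
      key <- paste(co, col, sep = ".")
      if (!is.null(dna_stats) && !is.null(dna_stats[[key]])) {
        m <- dna_stats[[key]][["mean"]]; s <- dna_stats[[key]][["sd"]]
      } else {
        m <- mean(v); s <- sd(v)
      }
      stats_used[[key]] <- c(mean = m, sd = s)
      if (!is.finite(s) || s == 0) {
        warnf("qc_filter: zero DNA spread in cohort %s; DNA rule disabled",
              co)
        next
      }
      dna_out[in_co] <- dna_out[in_co] | v < m - dna_sd * s | v > m + dna_sd * s
    }
  }
  keep <- !(small | dna_out)
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_removed") <- c(area = sum(small),
                               dna = sum(dna_out & !small))
  attr(out, "dna_stats") <- stats_used
  out
}

#' Default gating configuration
#'
#' Ordered threshold-gating rules assigning each cell to one of the 15
#' populations (or `unclassified`). A marker call is positive when its
#' arcsinh-transformed intensity exceeds the marker threshold; rules are
#' evaluated in order and the first match wins, making the gate
#' deterministic and total. Thresholds default to the midpoint of the
#' synthetic marker model's positive and negative locations.
#'
#' @param thresholds Named numeric vector of per-marker thresholds on the
#'   transformed scale; unnamed markers fall back to `default_threshold`.
#' @param default_threshold Fallback threshold.
#' @return Object of class `gating_config`.
#' @export
gating_config <- function(thresholds = NULL,
                          default_threshold = (MARKER_MU_POS +
                                                 MARKER_MU_NEG) / 2) {
  rules <- list(
    list(label = "tumor_prolif", pos = c("panCK", "Ki67"), neg = character(0)),
    list(label = "tumor_nonprolif", pos = "panCK", neg = "Ki67"),
    list(label = "cd4_treg", pos = c("CD45", "CD3", "CD4", "FoxP3"),
         neg = character(0)),
    list(label = "cd4_naive", pos = c("CD45", "CD3", "CD4", "CD45RA"),
         neg = "FoxP3"),
    list(label = "cd4_memory", pos = c("CD45", "CD3", "CD4"),
         neg = c("FoxP3", "CD45RA")),
    list(label = "cd8_t", pos = c("CD45", "CD3", "CD8"), neg = character(0)),
    list(label = "b_cell", pos = c("CD45", "CD20"), neg = character(0)),
    list(label = "m2_mac", pos = c("CD68", "CD163", "CD206"),
         neg = character(0)),
    list(label = "m1_mac", pos = "CD68", neg = "CD206"),
    list(label = "mdsc", pos = c("CD14", "CD11b"), neg = "HLADR"),
    list(label = "monocyte", pos = "CD14", neg = "CD68"),
    list(label = "granulocyte", pos = c("CD11b", "GranzymeB"), neg = "CD14"),
    list(label = "dendritic", pos = "CD11c", neg = character(0)),
    list(label = "vessel", pos = character(0), neg = character(0),
         any_pos = c("CD31", "aSMA")),
    list(label = "fibroblast", pos = "collagen", neg = character(0))
  )
  used <- unique(unlist(lapply(rules, function(r)
    c(r$pos, r$neg, r$any_pos))))
  thr <- setNames(rep(default_threshold, length(used)), used)
  if (!is.null(thresholds)) thr[names(thresholds)] <- thresholds
  structure(list(rules = rules, thresholds = thr), class = "gating_config")
}

#' Assign cell types by deterministic marker gating
#'
#' Applies the ordered gating rules of a [gating_config()] to the
#' arcsinh-transformed marker intensities. Every cell receives exactly one
#' label; cells matching no rule are `unclassified`. A plug-in path for
#' externally computed labels (e.g., graph-based clustering run outside
#' this package) is provided via `external_labels`.
#'
#' @param cells Cell table with `raw_<marker>` columns.
#' @param gating A [gating_config()].
#' @param cofactor Arcsinh cofactor.
#' @param external_labels Optional character vector of precomputed labels
#'   (length `nrow(cells)`), used verbatim instead of gating.
#' @return `cells` with a `type_label` column.
#' @export
gate_cell_types <- function(cells, gating = gating_config(), cofactor = 1,
                            external_labels = NULL) {
  if (!is.null(external_labels)) {
    stopifnot(length(external_labels) == nrow(cells))
    cells$type_label <- as.character(external_labels)
    return(cells)
  }
  used <- names(gating$thresholds)
  missing_m <- used[!paste0("raw_", used) %in% names(cells)]
  if (length(missing_m) > 0)
    stopf("gating rules reference missing marker(s): %s",
          paste(missing_m, collapse = ", "))
  tm <- sapply(used, function(m)
    arcsinh_transform(cells[[paste0("raw_", m)]], cofactor) >
      gating$thresholds[m])
  if (nrow(cells) == 1) tm <- matrix(tm, nrow = 1, dimnames = list(NULL, used))
  lab <- rep("unclassified", nrow(cells))
  undecided <- rep(TRUE, nrow(cells))
  for (r in gating$rules) {
    hit <- undecided
    for (m in r$pos) hit <- hit & tm[, m]
    for (m in r$neg) hit <- hit & !tm[, m]
    if (!is.null(r$any_pos)) {
      anyp <- rep(FALSE, nrow(cells))
      for (m in r$any_pos) anyp <- anyp | tm[, m]
      hit <- hit & anyp
    }
    lab[hit] <- r$label
    undecided <- undecided & !hit
  }
  cells$type_label <- lab
  cells
}

#' Eccentricity of a pixel region
#'
#' Eccentricity of the second-moment ellipse of a pixel set:
#' `sqrt(1 - l_minor/l_major)` on the eigenvalues of the central second-moment
#' matrix, with the 1/12 pixel-extent correction so single pixels and
#' straight lines stay within `[0, 1)`. 0 for a disk, approaching 1 for a
#' line.
#'
#' @param rows,cols Pixel coordinates of the region.
#' @return Eccentricity in `[0, 1)`.
#' @export
eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n == 0) stopf("empty region")
  if (n == 1) return(0)
  mu20 <- stats::var(rows) * (n - 1) / n + 1 / 12
  mu02 <- stats::var(cols) * (n - 1) / n + 1 / 12
  mu11 <- stats::cov(rows, cols) * (n - 1) / n
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  sqrt(max(1 - l2 / l1, 0))
}

# Region properties (area um^2, centroid um, eccentricity) for every label
# in a label mask.
region_props <- function(label_mask, pixel_size = 1) {
  idx <- which(label_mask > 0)
  labs <- label_mask[idx]
  nr <- nrow(label_mask)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  sp <- split(seq_along(labs), labs)
  out <- data.frame(
    cell_id = as.integer(names(sp)),
    area = vapply(sp, length, 1L) * pixel_size^2,
    x = vapply(sp, function(i) mean(cols[i]) - 0.5, 1) * pixel_size,
    y = vapply(sp, function(i) mean(rows[i]) - 0.5, 1) * pixel_size,
    eccentricity = vapply(sp, function(i) eccentricity(rows[i], cols[i]), 1),
    row.names = NULL)
  out
}
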