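#' Zoning configuration
#'
#' Parameters controlling the partition of a region of interest (ROI) into
#' stroma, tumor front, and tumor core relative to the tumor border.
#'
#' The tumor front is the band of half-width `band_halfwidth` straddling the
#' tumor border on both sides: a cell (or pixel) belongs to the core if its
#' signed border distance is below `-band_halfwidth`, to the front if the
#' absolute distance is at most `band_halfwidth` (closed interval, so exact
#' ties at the band edge fall into the front), and to the stroma otherwise.
#'
#' @param band_halfwidth Half-width of the tumor-front band in micrometres.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @return An object of class `zone_config`.
#' @export
zone_config <- function(band_halfwidth = 20, pixel_size = 1) {
  if (!is.numeric(band_halfwidth) || band_halfwidth <= 0)
    stopf("band_halfwidth must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0")
  structure(list(band_halfwidth = band_halfwidth, pixel_size = pixel_size),
            class = "zone_config")
}

# Border pixel set: foreground pixels 4-adjacent to background. The image
# edge is not treated as background, so a full-foreground mask has no border.
border_pixels <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  nb <- matrix(FALSE, nr, nc)
  if (nr > 1) {
    nb[-1, ] <- nb[-1, ] | !mask[-nr, ]
    nb[-nr, ] <- nb[-nr, ] | !mask[-1, ]
  }
  if (nc > 1) {
    nb[, -1] <- nb[, -1] | !mask[, -nc]
    nb[, -nc] <- nb[, -nc] | !mask[, -1]
  }
  mask & nb
}

#' Signed Euclidean distance to the tumor border
#'
#' Computes, for every pixel, the exact Euclidean distance (pixel
#' center-to-center, scaled to micrometres) to the nearest tumor border
#' pixel, signed negative inside the tumor and positive outside. Border
#' pixels (tumor pixels 4-adjacent to background) have distance 0.
#'
#' Degenerate masks carry sentinels: with no tumor anywhere every pixel is
#' `+Inf` (stroma side); with tumor everywhere (no border, since the image
#' edge does not count as background) every pixel is `-Inf`. Both cases are
#' flagged in the result.
#'
#' @param tumor_mask Logical or 0/1 matrix; `TRUE`/1 marks tumor.
#' @param config A [zone_config()].
#' @return A list of class `signed_distance_map` with elements `distance`
#'   (matrix, micrometres), `degenerate` (`"none"`, `"empty"` or `"full"`).
#' @export
signed_border_distance <- function(tumor_mask, config = zone_config()) {
  if (!is.matrix(tumor_mask)) stopf("tumor_mask must be a matrix")
  vals <- unique(as.vector(tumor_mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stopf("tumor_mask must be binary (0/1)")
  mask <- tumor_mask > 0
  n_fg <- sum(mask)
  if (n_fg == 0) {
    d <- matrix(Inf, nrow(mask), ncol(mask))
    return(structure(list(distance = d, degenerate = "empty"),
                     class = "signed_distance_map"))
  }
  border <- border_pixels(mask)
  if (!any(border)) {
    # tumor everywhere: no border exists
    d <- matrix(-Inf, nrow(mask), ncol(mask))
    return(structure(list(distance = d, degenerate = "full"),
                     class = "signed_distance_map"))
  }
  d2 <- edt_squared(border)
  d <- sqrt(d2) * config$pixel_size
  d[mask] <- -d[mask]
  # border pixels are foreground with distance 0; the sign flip leaves -0,
  # normalize to exactly 0
  d[border] <- 0
  structure(list(distance = d, degenerate = "none"),
            class = "signed_distance_map")
}

# Boundary pixels of every labelled cell: cell pixels 4-adjacent to a pixel
# with a different label (background = 0 counts as different); image-edge
# pixels of a cell count as boundary. Returns a logical matrix.
label_boundary <- function(label_mask) {
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  b <- matrix(FALSE, nr, nc)
  lm <- label_mask
  if (nr > 1) {
    b[-1, ] <- b[-1, ] | (lm[-1, ] != lm[-nr, ])
    b[-nr, ] <- b[-nr, ] | (lm[-nr, ] != lm[-1, ])
  }
  if (nc > 1) {
    b[, -1] <- b[, -1] | (lm[, -1] != lm[, -nc])
    b[, -nc] <- b[, -nc] | (lm[, -nc] != lm[, -1])
  }
  b[1, ] <- TRUE; b[nr, ] <- TRUE; b[, 1] <- TRUE; b[, nc] <- TRUE
  b & (label_mask > 0)
}

#' Per-cell signed distance to the tumor border
#'
#' For every labelled cell, returns the signed border distance of minimal
#' absolute value over the cell's boundary pixels. Cells overlapping the
#' tumor border therefore get 0.
#'
#' @param label_mask Integer matrix of cell labels (0 = background).
#' @param dist A [signed_border_distance()] result with the same shape.
#' @param cell_ids Optional integer vector of cell ids expected in the mask;
#'   ids absent from the mask raise a consistency error.
#' @return Named numeric vector of signed distances (micrometres), names are
#'   cell labels.
#' @export
cell_border_distance <- function(label_mask, dist, cell_ids = NULL) {
  if (!all(dim(label_mask) == dim(dist$distance)))
    stopf("label mask and distance map shapes differ")
  bnd <- label_boundary(label_mask)
  labs <- label_mask[bnd]
  dvals <- dist$distance[bnd]
  if (!is.null(cell_ids)) {
    missing_ids <- setdiff(cell_ids, unique(as.vector(label_mask)))
    if (length(missing_ids) > 0)
      stopf("cell id(s) absent from label mask: %s",
            paste(head(missing_ids, 5), collapse = ", "))
  }
  # per cell: value of minimal |d|, keeping its sign
  ord <- order(labs, abs(dvals))
  labs <- labs[ord]; dvals <- dvals[ord]
  first <- !duplicated(labs)
  setNames(dvals[first], labs[first])
}

#' Assign cells to tissue zones
#'
#' Maps signed border distances to zones: core below `-band_halfwidth`,
#' front within the closed band, stroma above `+band_halfwidth`. With no
#' tumor present (`+Inf` sentinel) all cells are stroma; with tumor
#' everywhere (`-Inf`) all cells are core.
#'
#' @param cell_distances Numeric vector of signed distances (micrometres).
#' @param config A [zone_config()].
#' @return Factor with levels `stroma`, `front`, `core`.
#' @export
assign_zones <- function(cell_distances, config = zone_config()) {
  b <- config$band_halfwidth
  z <- ifelse(cell_distances < -b, "core",
              ifelse(cell_distances > b, "stroma", "front"))
  factor(z, levels = ZONES)
}

#' Zone areas of an ROI
#'
#' Partitions the ROI by distance thresholds on the signed border distance:
#' the expanded tumor area `A_e` collects pixels within `band_halfwidth` of
#' the border on the outside or anywhere inside (distance <= +b), the
#' shrunken tumor area `A_s` collects pixels deeper than `band_halfwidth`
#' inside (distance < -b). Stroma area is `A_ROI - A_e`, front is
#' `A_e - A_s`, core is `A_s`. Using distance thresholds (not
#' structuring-element morphology) makes pixel zones and areas consistent by
#' construction. Areas are reported in mm^2.
#'
#' @param tumor_mask Binary matrix.
#' @param config A [zone_config()].
#' @param dist Optional precomputed [signed_border_distance()] map.
#' @return A list of class `zone_map`: `zone_image` (factor-coded integer
#'   matrix 1=stroma, 2=front, 3=core), `n_px_roi` and `zone_px` (pixel
#'   counts, exact partition), `area_roi`, `area_tumor`, `area_expanded`,
#'   `area_shrunk`, `zone_areas` (named, mm^2), `degenerate`.
#' @export
zone_areas <- function(tumor_mask, config = zone_config(), dist = NULL) {
  if (is.null(dist)) dist <- signed_border_distance(tumor_mask, config)
  d <- dist$distance
  b <- config$band_halfwidth
  px_mm2 <- (config$pixel_size^2) / 1e6
  n_roi <- length(d)
  zone_image <- matrix(1L, nrow(d), ncol(d))
  zone_image[abs(d) <= b] <- 2L
  zone_image[d < -b] <- 3L
  n_e <- sum(d <= b)
  n_s <- sum(d < -b)
  n_t <- sum(tumor_mask > 0)
  areas <- c(stroma = (n_roi - n_e) * px_mm2,
             front = (n_e - n_s) * px_mm2,
             core = n_s * px_mm2)
  zone_px <- c(stroma = n_roi - n_e, front = n_e - n_s, core = n_s)
  structure(list(zone_image = zone_image,
                 n_px_roi = n_roi, zone_px = zone_px,
                 area_roi = n_roi * px_mm2,
                 area_tumor = n_t * px_mm2,
                 area_expanded = n_e * px_mm2,
                 area_shrunk = n_s * px_mm2,
                 zone_areas = areas,
                 degenerate = dist$degenerate),
            class = "zone_map")
}

#' Tumor-covered fraction of an ROI
#'
#' @param zone_map A [zone_areas()] result.
#' @return `area_tumor / area_roi`, in `[0, 1]`.
#' @export
tumor_covered_fraction <- function(zone_map) {
  zone_map$area_tumor / zone_map$area_roi
}
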