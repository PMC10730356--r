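# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (explicit loops, O(n^2) scans) so they share no code
# path with the package implementations they check.

# --- geometry oracles -------------------------------------------------------

# border pixels by explicit neighbor inspection (4-adjacency; image edge is
# not background)
bf_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !mask[ii, jj]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

# signed distance by exhaustive min over border pixels
bf_signed_distance <- function(mask, pixel_size = 1) {
  mask <- mask > 0
  b <- which(bf_border(mask), arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(if (sum(mask) == 0) Inf else -Inf, nr, nc)
  if (nrow(b) == 0) return(d)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dd <- sqrt(min((b[, 1] - i)^2 + (b[, 2] - j)^2)) * pixel_size
    d[i, j] <- if (mask[i, j]) -dd else dd
  }
  d
}

# per-cell signed distance: min |d| over the cell's boundary pixels
bf_cell_distance <- function(label_mask, dmat) {
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  ids <- sort(setdiff(unique(as.vector(label_mask)), 0))
  out <- setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    best <- Inf; bestv <- NA_real_
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (label_mask[i, j] != ids[k]) next
      on_boundary <- i == 1 || i == nr || j == 1 || j == nc
      if (!on_boundary) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          if (label_mask[i + d[1], j + d[2]] != ids[k]) {
            on_boundary <- TRUE
            break
          }
        }
      }
      if (on_boundary && abs(dmat[i, j]) < best) {
        best <- abs(dmat[i, j])
        bestv <- dmat[i, j]
      }
    }
    out[k] <- bestv
  }
  out
}

bf_zone <- function(d, band = 20) {
  if (d < -band) "core" else if (d > band) "stroma" else "front"
}

# random binary mask + non-overlapping square cells on a small grid
random_zoning_fixture <- function(seed, max_dim = 64) {
  set.seed(seed)
  nr <- sample(16:max_dim, 1); nc <- sample(16:max_dim, 1)
  mask <- generate_tumor_mask(c(nr, nc), runif(1, 0.1, 0.8),
                              seed = seed * 3 + 1, smoothness = 10)
  lab <- matrix(0L, nr, nc)
  id <- 0L
  for (try in 1:40) {
    sz <- sample(2:3, 1)
    i <- sample(seq_len(nr - sz + 1), 1)
    j <- sample(seq_len(nc - sz + 1), 1)
    blk <- lab[i:(i + sz - 1), j:(j + sz - 1)]
    if (all(blk == 0)) {
      id <- id + 1L
      lab[i:(i + sz - 1), j:(j + sz - 1)] <- id
    }
  }
  list(mask = mask, label = lab)
}

# --- neighborhood oracle ----------------------------------------------------

# O(n^2) neighborhood coefficients: per center cell, up to k nearest
# neighbors within max_dist (radius-corrected distance when radii given);
# returns per-cell proportion vectors and the per-(zone, center) means.
bf_neighborhood <- function(cells, k = 5, max_dist = 20, radii = NULL,
                            populations = sort(unique(cells$population))) {
  n <- nrow(cells)
  percell <- vector("list", n)
  for (i in seq_len(n)) {
    dists <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (!is.null(radii)) d <- max(d - radii[i] - radii[j], 0)
      dists[j] <- d
    }
    ok <- which(dists <= max_dist)
    ok <- ok[order(dists[ok], ok)]
    nb <- head(ok, k)
    if (length(nb) == 0) { percell[[i]] <- NULL; next }
    pr <- sapply(populations, function(p) mean(cells$population[nb] == p))
    percell[[i]] <- pr
  }
  means <- list()
  for (z in unique(cells$zone)) for (p in populations) {
    rows <- which(cells$zone == z & cells$population == p &
                    !vapply(percell, is.null, TRUE))
    if (length(rows) == 0) next
    means[[paste(z, p, sep = "|")]] <-
      colMeans(do.call(rbind, percell[rows]))
  }
  list(percell = percell, means = means)
}

# --- shared medium cohort (generated once per test run) ---------------------

cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(cohort_cache$co)) {
    cohort_cache$co <- generate_cohort(
      cohort_config(n_patients = 8, roi_shape = c(300, 600), seed = 101))
  }
  cohort_cache$co
}
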