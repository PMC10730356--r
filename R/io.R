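# Conventions: coordinates are pixel-grid, row-major, (row, col) order with
# physical units in micrometres (pixel_size in config); tumor masks are
# 8-bit binary TIFF, label masks 16-bit TIFF; tables CSV; reports JSON.

#' Write a binary or label mask as TIFF
#'
#' Binary masks are written 8-bit, label masks 16-bit; both round-trip
#' exactly through [read_mask_tiff()].
#'
#' @param mask Logical or integer matrix (labels < 65536).
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  if (is.logical(mask) || all(mask %in% c(0, 1))) {
    tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                    bits.per.sample = 8)
  } else {
    if (max(mask) > 65535) stopf("label values exceed 16-bit range")
    tiff::writeTIFF(matrix(as.numeric(mask) / 65535, nrow(mask)), path,
                    bits.per.sample = 16)
  }
  invisible(path)
}

#' Read a mask TIFF written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @param binary If `TRUE`, return a logical matrix; otherwise integer
#'   labels.
#' @return Matrix.
#' @export
read_mask_tiff <- function(path, binary = FALSE) {
  m <- tiff::readTIFF(path)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  if (binary) return(m > 0.5)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Read and validate one ROI bundle
#'
#' Loads a label mask, a tumor mask and a cell table, checking shape
#' agreement, binarity of the tumor mask, required cell-table columns and
#' the containment of table cell ids in the label mask.
#'
#' @param label_mask_path,tumor_mask_path,cell_table_path File paths.
#' @param roi_id Identifier used in error messages.
#' @return List `label_mask`, `tumor_mask`, `cells`.
#' @export
read_roi_bundle <- function(label_mask_path, tumor_mask_path,
                            cell_table_path, roi_id = "?") {
  label_mask <- read_mask_tiff(label_mask_path)
  tm_raw <- tiff::readTIFF(tumor_mask_path)
  if (is.array(tm_raw) && length(dim(tm_raw)) == 3) tm_raw <- tm_raw[, , 1]
  vals <- unique(round(as.vector(tm_raw) * 255))
  if (!all(vals %in% c(0, 255)) && !all(vals %in% c(0, 1)))
    stopf("ROI %s: tumor mask is not binary (values: %s)", roi_id,
          paste(head(sort(vals), 5), collapse = ", "))
  tumor_mask <- tm_raw > 0.5
  if (!all(dim(label_mask) == dim(tumor_mask)))
    stopf("ROI %s: mask shapes differ", roi_id)
  cells <- read.csv(cell_table_path, stringsAsFactors = FALSE)
  required <- c("cell_id", "roi_id", "x", "y")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stopf("ROI %s: cell table lacks column(s): %s", roi_id,
          paste(missing_cols, collapse = ", "))
  mask_ids <- unique(as.vector(label_mask))
  orphans <- setdiff(cells$cell_id, mask_ids)
  if (length(orphans) > 0)
    stopf("ROI %s: cell id(s) missing from label mask: %s", roi_id,
          paste(head(orphans, 5), collapse = ", "))
  list(label_mask = label_mask, tumor_mask = tumor_mask, cells = cells)
}

#' Write a synthetic cohort to disk
#'
#' Cell table and zone/metadata tables as CSV, masks (when kept) as TIFF,
#' the generator configuration as YAML, and a manifest JSON tying ROIs to
#' patients and recording the seed and a configuration hash.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(cohort$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- lapply(cfg, function(v) {
    if (is.data.frame(v) || is.matrix(v)) NULL else if (is.list(v)) NULL
    else v
  })
  yaml::write_yaml(Filter(Negate(is.null), cfg_list),
                   file.path(dir, "config.yaml"))
  if (!is.null(cohort$masks)) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (r in seq_along(cohort$masks)) {
      roi <- cohort$meta$roi_id[r]
      write_mask_tiff(cohort$masks[[r]]$tumor_mask,
                      file.path(mdir, paste0(roi, "_tumor.tiff")))
      if (!is.null(cohort$masks[[r]]$label_mask))
        write_mask_tiff(cohort$masks[[r]]$label_mask,
                        file.path(mdir, paste0(roi, "_labels.tiff")))
    }
  }
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   n_patients = cfg$n_patients,
                   rois = cohort$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List `cells`, `zones`, `meta`, `manifest`.
#' @export
read_cohort <- function(dir) {
  list(cells = read.csv(file.path(dir, "cells.csv"),
                        stringsAsFactors = FALSE),
       zones = read.csv(file.path(dir, "zones.csv"),
                        stringsAsFactors = FALSE),
       meta = read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

# Stable short hash of a configuration (djb2 over its serialized form).
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 10)),
             collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Write a feature matrix (values + annotations) as CSV
#'
#' @param fm A [feature_matrix].
#' @param dir Output directory.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(roi_id = fm$row_info$roi_id, fm$x,
                       check.names = FALSE),
            file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(fm$col_info, file.path(dir, "feature_annotations.csv"),
            row.names = FALSE)
  write.csv(fm$row_info, file.path(dir, "sample_annotations.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param dir Directory.
#' @return A [feature_matrix].
#' @export
read_feature_matrix <- function(dir) {
  vals <- read.csv(file.path(dir, "features.csv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  x <- as.matrix(vals[, -1, drop = FALSE])
  rownames(x) <- vals$roi_id
  feature_matrix(x,
                 read.csv(file.path(dir, "feature_annotations.csv"),
                          stringsAsFactors = FALSE),
                 read.csv(file.path(dir, "sample_annotations.csv"),
                          stringsAsFactors = FALSE))
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> phenotype/QC -> features -> variability ->
#' model, writing each stage's artifacts under `out_dir` together with a
#' manifest (seed, configuration hash, stage timings). Stages whose outputs
#' already exist are skipped, so a partial run resumes from its on-disk
#' intermediates.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param stability A [stability_config()] for the modeling stage.
#' @param stages Character subset of
#'   `c("simulate", "features", "variability", "model")`.
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         stability = stability_config(),
                         stages = c("simulate", "features", "variability",
                                    "model")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  out <- list()

  cohort_dir <- file.path(out_dir, "cohort")
  if ("simulate" %in% stages) {
    if (file.exists(file.path(cohort_dir, "cells.csv"))) {
      message("simulate: outputs exist, skipping")
      out$cohort <- read_cohort(cohort_dir)
    } else {
      t0 <- Sys.time()
      cohort <- generate_cohort(config)
      cohort$cells <- gate_cell_types(qc_filter(cohort$cells,
                                                pixel_size = config$pixel_size))
      write_cohort(cohort, cohort_dir)
      timings$simulate <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      out$cohort <- cohort
    }
  }

  feat_dir <- file.path(out_dir, "features")
  if ("features" %in% stages) {
    if (file.exists(file.path(feat_dir, "features.csv"))) {
      message("features: outputs exist, skipping")
      out$features <- read_feature_matrix(feat_dir)
    } else {
      t0 <- Sys.time()
      co <- out$cohort %||% read_cohort(cohort_dir)
      cells <- co$cells
      # features are computed on the gated labels
      if ("type_label" %in% names(cells)) cells$population <- cells$type_label
      cells <- cells[cells$population != "unclassified", , drop = FALSE]
      fm <- assemble_feature_matrix(cells, co$zones, co$meta)
      write_feature_matrix(fm, feat_dir)
      timings$features <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      out$features <- fm
    }
  }

  if ("variability" %in% stages) {
    var_path <- file.path(out_dir, "variability.json")
    if (file.exists(var_path)) {
      message("variability: outputs exist, skipping")
    } else {
      t0 <- Sys.time()
      fm <- out$features %||% read_feature_matrix(feat_dir)
      dens <- fm$x[, fm$col_info$feature_class == "density", drop = FALSE]
      cvr <- cv_report(dens, fm$row_info$patient_id,
                       seed = derive_seed(config$seed, 31L))
      res <- list(median_intrapatient_cv =
                    median(cvr$intrapatient, na.rm = TRUE),
                  median_interpatient_cv =
                    median(cvr$interpatient, na.rm = TRUE))
      jsonlite::write_json(res, var_path, auto_unbox = TRUE, digits = NA)
      timings$variability <- as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))
      out$variability <- res
    }
  }

  if ("model" %in% stages) {
    model_path <- file.path(out_dir, "model.json")
    if (file.exists(model_path)) {
      message("model: outputs exist, skipping")
    } else {
      t0 <- Sys.time()
      fm <- out$features %||% read_feature_matrix(feat_dir)
      res <- monte_carlo_cv(fm, stability)
      report <- list(auc = res$auc$auc, ci = res$auc$ci, p = res$auc$p,
                     selected = res$final$selected,
                     coefficients = as.list(res$final$model$coef),
                     seed = stability$seed)
      jsonlite::write_json(report, model_path, auto_unbox = TRUE,
                           digits = NA)
      timings$model <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      out$model <- res
    }
  }

  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         timings = timings),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
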