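# Readers/writers for the cell and clinical CSV schemas, and the top-level
# orchestration that chains metrics -> aggregation -> comparisons ->
# survival.
#
# CSV dialect: comma-separated, UTF-8, '.' decimal, header row required.
# Missing values are empty fields, never sentinel numbers.

CELLS_COLS <- c("patient_id", "sample_id", "sample_role", "roi_id",
                "x_um", "y_um", "cell_class", "cd68", "cd163", "cd206",
                "pdl1")
CLINICAL_COLS <- c("patient_id", "age", "imdc", "os_months", "event")

#' Read a per-cell coordinate CSV into marked point patterns
#'
#' One row per cell with columns `patient_id, sample_id, sample_role,
#' roi_id, x_um, y_um, cell_class, cd68, cd163, cd206, pdl1` (HALO-style
#' export converted to this schema). Windows come from an optional sidecar
#' table `rois` (`roi_id, width_um, height_um`); ROIs without a sidecar row
#' use the default 678 x 506 um window. Coordinates outside the window or
#' unknown classes abort with the offending row numbers.
#'
#' @param path CSV file path, or a data.frame already in the schema.
#' @param rois optional data.frame (`roi_id, width_um, height_um`) or CSV
#'   path.
#' @param default_window window for ROIs not listed in `rois`.
#' @return Named list of `mpp` objects, one per `roi_id` (in order of first
#'   appearance).
#' @export
read_cells_csv <- function(path, rois = NULL, default_window = pp_window()) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CELLS_COLS, names(df))
  if (length(miss)) {
    stop("cells table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(rois) && !is.data.frame(rois)) {
    rois <- utils::read.csv(rois, stringsAsFactors = FALSE)
  }
  roi_window <- function(rid) {
    if (!is.null(rois) && rid %in% rois$roi_id) {
      r <- rois[match(rid, rois$roi_id), ]
      pp_window(r$width_um, r$height_um)
    } else default_window
  }
  roi_ids <- unique(df$roi_id)
  out <- lapply(roi_ids, function(rid) {
    rows <- df[df$roi_id == rid, , drop = FALSE]
    w <- roi_window(rid)
    bad <- rows$x_um < w$x_min | rows$x_um > w$x_max |
           rows$y_um < w$y_min | rows$y_um > w$y_max
    if (any(bad, na.rm = TRUE) || anyNA(rows$x_um) || anyNA(rows$y_um)) {
      stop("ROI '", rid, "': coordinates outside window at input row(s) ",
           paste(utils::head(rownames(rows)[bad | is.na(rows$x_um) |
                                              is.na(rows$y_um)], 5),
                 collapse = ", "), call. = FALSE)
    }
    cells <- data.frame(x = rows$x_um, y = rows$y_um,
                        cell_class = rows$cell_class,
                        rows[MARKER_NAMES], stringsAsFactors = FALSE)
    marked_point_pattern(cells, w, roi_id = rid,
                         sample_id = rows$sample_id[1],
                         patient_id = rows$patient_id[1],
                         sample_role = rows$sample_role[1])
  })
  names(out) <- roi_ids
  out
}

#' Write marked point patterns to the cells CSV schema
#'
#' @param patterns a single `mpp` or a list of them.
#' @param path output CSV path; `NULL` returns the data.frame invisibly
#'   without writing.
#' @return The assembled data.frame, invisibly.
#' @export
write_cells_csv <- function(patterns, path = NULL) {
  if (inherits(patterns, "mpp")) patterns <- list(patterns)
  rows <- lapply(patterns, function(p) {
    cells <- p$cells
    data.frame(patient_id = p$patient_id, sample_id = p$sample_id,
               sample_role = p$sample_role, roi_id = p$roi_id,
               x_um = cells$x, y_um = cells$y, cell_class = cells$cell_class,
               cells[MARKER_NAMES], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(df)
}

#' Read the per-patient clinical CSV
#'
#' Columns: `patient_id, age, imdc, os_months, event` with IMDC risk group
#' in {"1", "2", "3+"}, overall-survival time in months (> 0) and a 0/1
#' death indicator.
#'
#' @param path CSV path or data.frame.
#' @return Validated data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(imdc = "character"))
  miss <- setdiff(CLINICAL_COLS, names(df))
  if (length(miss)) {
    stop("clinical table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$imdc <- as.character(df$imdc)
  if (any(!df$imdc %in% c("1", "2", "3+"))) {
    stop("imdc must be one of 1, 2, 3+", call. = FALSE)
  }
  if (any(df$os_months <= 0) || any(!df$event %in% c(0, 1))) {
    stop("os_months must be > 0 and event 0/1", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id in clinical table", call. = FALSE)
  }
  df
}

#' Run the full spatial-survival analysis
#'
#' Chains the pipeline end to end on already-classified cell tables:
#' per-ROI densities and nK(25) metrics with eligibility filtering ->
#' patient-level aggregation over primary-sample ROIs -> per-marker
#' compartment-affinity tests and the density-vs-clustering Spearman
#' correlation -> optimal cut-point dichotomization of the density and
#' clustering variables -> multivariable Cox regression (both dichotomized
#' variables jointly, plus clinical covariates) with Kaplan-Meier curves
#' and the cohort's minimum detectable hazard ratio. Deterministic given
#' its inputs.
#'
#' @param cells cells CSV path or data.frame ([read_cells_csv()] schema).
#' @param clinical clinical CSV path or data.frame.
#' @param rois optional ROI window sidecar (see [read_cells_csv()]).
#' @param radius search radius in um (default 25).
#' @param min_count eligibility cell-count threshold (default 10).
#' @param agg patient-level aggregation rule (default `"mean"`).
#' @param marker marker driving the survival analysis (default `"cd68"`).
#' @param covariates clinical covariates for the Cox model (default age and
#'   IMDC risk group).
#' @param min_group_frac,min_group_size cut-point scan constraints
#'   (defaults: 10% of patients, at least 3).
#' @param out_dir optional directory; when given, writes `roi_metrics.csv`,
#'   `patients.csv`, `comparisons.json` and `survival.json` there.
#' @return list: `roi_metrics`, `patients`, `comparisons` (per marker),
#'   `correlation`, `cutpoints` (density and clustering), `cox` (joint
#'   model), `cox_combined` (single high-density AND high-clustering
#'   stratum), `km` (per-stratum curves), `mdhr`.
#' @export
run_full_analysis <- function(cells, clinical, rois = NULL, radius = 25,
                              min_count = 10, agg = "mean", marker = "cd68",
                              covariates = c("age", "imdc"),
                              min_group_frac = 0.10, min_group_size = 3L,
                              out_dir = NULL) {
  patterns <- read_cells_csv(cells, rois = rois)
  clin <- read_clinical_csv(clinical)
  rm_df <- compute_all_roi_metrics(patterns, radius = radius,
                                   min_count = min_count)
  patients <- aggregate_to_patient(rm_df, clin, role = "primary", agg = agg)

  comparisons <- lapply(MARKER_NAMES, function(m) {
    tryCatch(compartment_comparison(rm_df, m), error = function(e) {
      list(marker = m, n_pairs = 0L, statistic = NA_real_,
           p_value = NA_real_, median_tumor = NA_real_,
           median_stroma = NA_real_, note = conditionMessage(e))
    })
  })
  names(comparisons) <- MARKER_NAMES
  correlation <- correlation_density_clustering(rm_df, marker)

  dens_var <- paste0("density_", marker)
  clus_var <- paste0("nk25_tumor_", marker)
  surv_df <- patients[!is.na(patients[[dens_var]]) &
                        !is.na(patients[[clus_var]]), , drop = FALSE]
  cut_dens <- optimal_cutpoint(surv_df[[dens_var]], surv_df$os_months,
                               surv_df$event, min_group_frac,
                               min_group_size)
  cut_clus <- optimal_cutpoint(surv_df[[clus_var]], surv_df$os_months,
                               surv_df$event, min_group_frac,
                               min_group_size)
  surv_df$high_density <- surv_df[[dens_var]] > cut_dens$cutpoint
  surv_df$high_clustering <- surv_df[[clus_var]] > cut_clus$cutpoint
  surv_df$high_both <- surv_df$high_density & surv_df$high_clustering

  cox <- cox_fit(surv_df, c("high_density", "high_clustering", covariates))
  cox_combined <- tryCatch(
    cox_fit(surv_df, c("high_both", covariates)),
    error = function(e) NULL)
  km <- lapply(split(surv_df, surv_df$high_clustering), function(d) {
    km_estimate(d$os_months, d$event)
  })
  names(km) <- paste0("high_clustering_", names(km))
  mdhr <- minimum_detectable_hr(nrow(surv_df),
                                p_event = mean(surv_df$event))

  res <- list(roi_metrics = rm_df, patients = patients,
              comparisons = comparisons, correlation = correlation,
              cutpoints = list(density = cut_dens, clustering = cut_clus),
              cox = cox, cox_combined = cox_combined, km = km, mdhr = mdhr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rm_df, file.path(out_dir, "roi_metrics.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(patients, file.path(out_dir, "patients.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(comparisons,
                         file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      list(cutpoints = lapply(res$cutpoints, unclass),
           cox = cox$coefficients,
           cox_combined = if (!is.null(cox_combined)) cox_combined$coefficients,
           correlation = correlation, mdhr = mdhr),
      file.path(out_dir, "survival.json"),
      auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
  }
  res
}
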