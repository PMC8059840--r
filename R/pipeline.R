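# Per-ROI metric computation, eligibility filtering, patient-level
# aggregation, and compartment-affinity comparisons.
#
# For each ROI the pipeline computes, per marker, the marker-positive cell
# density (cells/mm^2) and the nK(25) of marker-positive cells around each
# compartment (tumor and stroma reference cells). ROIs with too few cells
# for a pairing — fewer than `min_count` marker-positive cells or fewer
# than `min_count` reference cells — are ineligible for that pairing and
# carry NA.

pair_col <- function(compartment, marker) paste0("nk25_", compartment, "_", marker)
elig_col <- function(compartment, marker) paste0("eligible_", compartment, "_", marker)

#' Eligibility of an ROI for spatial analysis of one pairing
#'
#' An ROI is eligible for the (compartment, marker) nK estimate when it
#' contains at least `min_count` marker-positive cells and at least
#' `min_count` compartment (reference) cells. The marker-count half is the
#' published >= 10-cell rule; requiring the same of the reference
#' compartment is deliberately stricter, avoiding K estimates anchored on a
#' handful of reference cells.
#'
#' @param pattern an `mpp`.
#' @param marker marker selector (e.g. `"cd68"`).
#' @param compartment reference compartment, `"tumor"` or `"stroma"`.
#' @param min_count minimum cell count (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(pattern, marker, compartment = "tumor",
                        min_count = 10) {
  stopifnot(inherits(pattern, "mpp"), min_count >= 1)
  n_cells(select_cells(pattern, marker)) >= min_count &&
    n_cells(select_cells(pattern, compartment)) >= min_count
}

#' Per-ROI densities and nK(25) metrics
#'
#' Computes marker-positive cell densities and, for every eligible
#' (compartment, marker) pairing in {tumor, stroma} x `markers`, the
#' nK(25) with reference = compartment cells and target = marker-positive
#' cells. Ineligible pairings are NA with the eligibility flag recording
#' why.
#'
#' @param pattern an `mpp`.
#' @param radius search radius, um (default 25).
#' @param min_count eligibility threshold (default 10).
#' @param markers marker subset to compute (default all four).
#' @return One-row data.frame: identifiers, total/compartment counts,
#'   `density_<marker>` columns, `nk25_<compartment>_<marker>` columns and
#'   matching `eligible_<compartment>_<marker>` flags.
#' @export
compute_roi_metrics <- function(pattern, radius = 25, min_count = 10,
                                markers = MARKER_NAMES) {
  stopifnot(inherits(pattern, "mpp"), radius > 0)
  markers <- match.arg(markers, MARKER_NAMES, several.ok = TRUE)
  out <- data.frame(
    roi_id = pattern$roi_id, sample_id = pattern$sample_id,
    patient_id = pattern$patient_id, sample_role = pattern$sample_role,
    n_cells = n_cells(pattern),
    n_tumor = n_cells(select_cells(pattern, "tumor")),
    n_stroma = n_cells(select_cells(pattern, "stroma")),
    stringsAsFactors = FALSE)
  for (m in markers) {
    out[[paste0("density_", m)]] <- cell_density(pattern, m)
    for (comp in c("tumor", "stroma")) {
      ok <- is_eligible(pattern, m, comp, min_count)
      out[[elig_col(comp, m)]] <- ok
      out[[pair_col(comp, m)]] <-
        if (ok) nk25(pattern, comp, m, radius = radius) else NA_real_
    }
  }
  out
}

#' Per-ROI metrics for a collection of patterns
#'
#' @param patterns a list of `mpp` objects (e.g. from [read_cells_csv()]).
#' @inheritParams compute_roi_metrics
#' @return data.frame with one row per ROI.
#' @export
compute_all_roi_metrics <- function(patterns, radius = 25, min_count = 10,
                                    markers = MARKER_NAMES) {
  stopifnot(length(patterns) >= 1)
  do.call(rbind, lapply(patterns, compute_roi_metrics, radius = radius,
                        min_count = min_count, markers = markers))
}

#' Aggregate ROI metrics to patient level
#'
#' Restricts to one sample role (survival analysis uses only the primary
#' tumor sample), then summarises each metric over the patient's eligible
#' ROIs — by default the unweighted mean of available values — and joins the
#' clinical table. Patients whose ROIs are all of the excluded role drop
#' out; a metric with no eligible ROI for a patient stays NA.
#'
#' @param roi_metrics data.frame from [compute_all_roi_metrics()].
#' @param clinical data.frame with columns patient_id, age, imdc,
#'   os_months, event; must cover every patient present in `roi_metrics`.
#' @param role sample role to keep (default `"primary"`).
#' @param agg `"mean"`, `"median"` or `"max"`.
#' @return data.frame with one row per patient: clinical columns, `n_rois`,
#'   and the aggregated `density_*` / `nk25_*` columns.
#' @export
aggregate_to_patient <- function(roi_metrics, clinical, role = "primary",
                                 agg = c("mean", "median", "max")) {
  agg <- match.arg(agg)
  stopifnot(is.data.frame(roi_metrics), is.data.frame(clinical))
  orphans <- setdiff(roi_metrics$patient_id, clinical$patient_id)
  if (length(orphans)) {
    stop("ROIs without a clinical row for patient(s): ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  keep <- roi_metrics[roi_metrics$sample_role == role, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("no ROIs with sample_role '", role, "'", call. = FALSE)
  }
  f <- switch(agg, mean = mean, median = stats::median, max = max)
  metric_cols <- grep("^(density_|nk25_)", names(keep), value = TRUE)
  agg_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) f(v) else NA_real_
  }
  pieces <- lapply(split(keep, keep$patient_id), function(df) {
    row <- data.frame(patient_id = df$patient_id[1], n_rois = nrow(df),
                      stringsAsFactors = FALSE)
    for (cc in metric_cols) row[[cc]] <- agg_one(df[[cc]])
    row
  })
  agg_df <- do.call(rbind, pieces)
  out <- merge(clinical, agg_df, by = "patient_id", all.x = FALSE,
               all.y = TRUE, sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Compartment-affinity comparison for one marker
#'
#' Paired Wilcoxon signed-rank test of tumor-anchored versus
#' stroma-anchored nK(25) across ROIs where both are available. Values > 1
#' for the tumor pairing and < 1 for the stroma pairing indicate the marker
#' population clusters into the tumor compartment, and vice versa.
#' Zero-difference pairs are dropped (standard signed-rank convention);
#' when every pair is tied the test is undefined and p = 1 is reported.
#'
#' @param roi_metrics data.frame from [compute_all_roi_metrics()].
#' @param marker marker name.
#' @return list: `marker`, `n_pairs`, `statistic` (V), `p_value`
#'   (two-sided), `median_tumor`, `median_stroma`.
#' @export
compartment_comparison <- function(roi_metrics, marker) {
  tu <- roi_metrics[[pair_col("tumor", marker)]]
  st <- roi_metrics[[pair_col("stroma", marker)]]
  if (is.null(tu) || is.null(st)) {
    stop("roi_metrics lacks nK columns for marker '", marker, "'",
         call. = FALSE)
  }
  ok <- !is.na(tu) & !is.na(st)
  if (!any(ok)) {
    stop("no ROI has both tumor and stroma nK(25) for marker '", marker,
         "'", call. = FALSE)
  }
  tu <- tu[ok]; st <- st[ok]
  if (all(tu == st)) {
    return(list(marker = marker, n_pairs = sum(ok), statistic = NA_real_,
                p_value = 1, median_tumor = stats::median(tu),
                median_stroma = stats::median(st)))
  }
  wt <- stats::wilcox.test(tu, st, paired = TRUE, exact = NULL)
  list(marker = marker, n_pairs = sum(ok),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       median_tumor = stats::median(tu), median_stroma = stats::median(st))
}

#' Spearman correlation of density and tumor-anchored clustering
#'
#' Rank correlation between per-ROI marker density and tumor/marker nK(25),
#' assessing whether the density and clustering metrics are redundant.
#'
#' @param roi_metrics data.frame from [compute_all_roi_metrics()].
#' @param marker marker name (default `"cd68"`).
#' @return list: `marker`, `n`, `rho`, `p_value` (rho is NA when either
#'   input is constant).
#' @export
correlation_density_clustering <- function(roi_metrics, marker = "cd68") {
  x <- roi_metrics[[paste0("density_", marker)]]
  y <- roi_metrics[[pair_col("tumor", marker)]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need >= 3 complete ROIs", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(marker = marker, n = length(x), rho = NA_real_,
                p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(marker = marker, n = length(x), rho = unname(ct$estimate),
       p_value = ct$p.value)
}
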