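# Marked point patterns on rectangular observation windows.
#
# A pattern holds the segmented cells of one region of interest (ROI):
# continuous coordinates in micrometres, a tumor/stroma/other cell class,
# and independent 0/1 positivity flags for the myeloid/immune markers.

#' Marker columns recognised throughout the package
#' @keywords internal
MARKER_NAMES <- c("cd68", "cd163", "cd206", "pdl1")

#' Cell classes recognised throughout the package
#' @keywords internal
CLASS_NAMES <- c("tumor", "stroma", "other")

#' Rectangular observation window
#'
#' Constructs the rectangular window of one ROI. Coordinates are continuous
#' micrometres with the origin at the lower-left corner; points exactly on
#' the boundary are inside. The default 678 x 506 um window corresponds to a
#' 1356 x 1012 pixel field digitised at 0.5 um/pixel.
#'
#' @param width_um,height_um window side lengths in micrometres (> 0).
#' @return An object of class `pp_window` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max` (um).
#' @examples
#' w <- pp_window()
#' roi_area_mm2(w) # 0.343068
#' @export
pp_window <- function(width_um = 678, height_um = 506) {
  if (!is.numeric(width_um) || !is.numeric(height_um) ||
      length(width_um) != 1L || length(height_um) != 1L ||
      !is.finite(width_um) || !is.finite(height_um) ||
      width_um <= 0 || height_um <= 0) {
    stop("window sides must be finite positive lengths in um", call. = FALSE)
  }
  structure(
    list(x_min = 0, x_max = as.numeric(width_um),
         y_min = 0, y_max = as.numeric(height_um)),
    class = "pp_window"
  )
}

window_width <- function(window) window$x_max - window$x_min
window_height <- function(window) window$y_max - window$y_min

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window: %g x %g um (%.6g mm^2)\n",
              window_width(x), window_height(x), roi_area_mm2(x)))
  invisible(x)
}

#' ROI area in square millimetres
#'
#' @param window a [pp_window()].
#' @return Window area in mm^2 (um^2 / 1e6).
#' @examples
#' roi_area_mm2(pp_window(678, 506)) # 0.343068
#' @export
roi_area_mm2 <- function(window) {
  stopifnot(inherits(window, "pp_window"))
  w <- window_width(window)
  h <- window_height(window)
  if (w <= 0 || h <= 0) stop("degenerate window", call. = FALSE)
  w * h / 1e6
}

area_um2 <- function(window) window_width(window) * window_height(window)

#' Marked point pattern of one ROI
#'
#' Bundles the cells of one ROI with its observation window and identifiers.
#' `cells` must have numeric `x`, `y` (um, inside the window, boundary
#' inclusive), a `cell_class` column with values in tumor/stroma/other, and
#' optional 0/1 marker columns `cd68`, `cd163`, `cd206`, `pdl1` (absent
#' columns are filled with 0). Marker flags are independent of cell class: a
#' CD68+ cell may be classed tumor, stroma or other, and a cell may carry
#' several flags. Duplicate coordinates are allowed.
#'
#' @param cells data.frame of cell records (may have zero rows).
#' @param window a [pp_window()].
#' @param roi_id,sample_id,patient_id identifiers.
#' @param sample_role `"primary"` or `"metastasis"`.
#' @return An object of class `mpp`.
#' @export
marked_point_pattern <- function(cells, window = pp_window(),
                                 roi_id = "roi1", sample_id = roi_id,
                                 patient_id = sample_id,
                                 sample_role = "primary") {
  stopifnot(inherits(window, "pp_window"), is.data.frame(cells))
  if (!sample_role %in% c("primary", "metastasis")) {
    stop("sample_role must be 'primary' or 'metastasis'", call. = FALSE)
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (nrow(cells) > 0) {
    need <- c("x", "y", "cell_class")
    miss <- setdiff(need, names(cells))
    if (length(miss)) {
      stop("cells is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    bad_class <- !cells$cell_class %in% CLASS_NAMES
    if (any(bad_class)) {
      stop("unknown cell_class at row(s) ",
           paste(utils::head(which(bad_class), 5), collapse = ", "),
           call. = FALSE)
    }
    out_x <- cells$x < window$x_min | cells$x > window$x_max
    out_y <- cells$y < window$y_min | cells$y > window$y_max
    if (any(out_x | out_y, na.rm = TRUE) || anyNA(cells$x) || anyNA(cells$y)) {
      stop("cell coordinates outside window (or NA) at row(s) ",
           paste(utils::head(which(out_x | out_y | is.na(cells$x) |
                                     is.na(cells$y)), 5), collapse = ", "),
           call. = FALSE)
    }
  } else {
    cells <- data.frame(x = numeric(0), y = numeric(0),
                        cell_class = character(0))
  }
  for (m in MARKER_NAMES) {
    if (is.null(cells[[m]])) cells[[m]] <- integer(nrow(cells))
    flag <- cells[[m]]
    if (anyNA(flag) || !all(flag %in% c(0, 1))) {
      stop("marker column '", m, "' must be 0/1", call. = FALSE)
    }
    cells[[m]] <- as.integer(flag)
  }
  cells <- cells[c("x", "y", "cell_class", MARKER_NAMES)]
  cells$.row <- seq_len(nrow(cells))  # record identity, survives select()
  structure(
    list(roi_id = roi_id, sample_id = sample_id, patient_id = patient_id,
         sample_role = sample_role, window = window, cells = cells),
    class = "mpp"
  )
}

#' Number of cells in a pattern
#' @param pattern an `mpp`.
#' @export
n_cells <- function(pattern) {
  stopifnot(inherits(pattern, "mpp"))
  nrow(pattern$cells)
}

#' @export
print.mpp <- function(x, ...) {
  cat(sprintf("marked point pattern '%s' (patient %s, %s sample): %d cells\n",
              x$roi_id, x$patient_id, x$sample_role, n_cells(x)))
  print(x$window)
  if (n_cells(x) > 0) {
    print(table(x$cells$cell_class))
  }
  invisible(x)
}

#' Select a sub-pattern by cell class or marker flag
#'
#' Selection by a marker name keeps every cell carrying that flag regardless
#' of its class; selection by class keeps that class regardless of flags.
#' Chained selections intersect. The window and identifiers are preserved, so
#' densities and K estimates of the sub-pattern refer to the original ROI.
#'
#' @param pattern an `mpp`.
#' @param selector one of `"tumor"`, `"stroma"`, `"other"`, `"cd68"`,
#'   `"cd163"`, `"cd206"`, `"pdl1"`.
#' @return An `mpp` containing only the matching cells.
#' @export
select_cells <- function(pattern, selector) {
  stopifnot(inherits(pattern, "mpp"))
  if (!is.character(selector) || length(selector) != 1L) {
    stop("selector must be a single string", call. = FALSE)
  }
  cells <- pattern$cells
  if (selector %in% CLASS_NAMES) {
    keep <- cells$cell_class == selector
  } else if (selector %in% MARKER_NAMES) {
    keep <- cells[[selector]] == 1L
  } else {
    stop("unknown selector '", selector, "'; expected a cell class (",
         paste(CLASS_NAMES, collapse = ", "), ") or marker (",
         paste(MARKER_NAMES, collapse = ", "), ")", call. = FALSE)
  }
  out <- pattern
  out$cells <- cells[keep, , drop = FALSE]
  out
}

#' Cell density in cells per square millimetre
#'
#' @param pattern an `mpp`.
#' @param selector optional class/marker selector; `NULL` counts all cells.
#' @return Count of (selected) cells divided by the window area in mm^2.
#' @examples
#' w <- pp_window(1000, 1000)
#' p <- marked_point_pattern(
#'   data.frame(x = runif(10, 0, 1000), y = runif(10, 0, 1000),
#'              cell_class = "tumor"), w)
#' cell_density(p) # 10 cells / mm^2
#' @export
cell_density <- function(pattern, selector = NULL) {
  stopifnot(inherits(pattern, "mpp"))
  p <- if (is.null(selector)) pattern else select_cells(pattern, selector)
  n_cells(p) / roi_area_mm2(pattern$window)
}
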