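#' Define a myocyte-model-input (MMI) space
#'
#' An MMI space is an ordered set of named axes, each with lower and upper
#' bounds in native units. It defines the region of interest over which
#' surrogate models are trained and fixes the min-max scaling used for all
#' feature construction.
#'
#' @param names character vector of unique axis names.
#' @param min,max numeric vectors of per-axis bounds (native units),
#'   `max > min` elementwise.
#' @param units character vector of unit labels (informational).
#' @return An object of class `mmi_space`: a data frame with columns
#'   `name`, `min`, `max`, `units`, one row per axis.
#' @examples
#' mmi_space(c("x", "y"), min = c(0, -1), max = c(1, 1))
#' @export
mmi_space <- function(names, min, max, units = rep("", length(names))) {
  names <- as.character(names)
  min <- as.numeric(min)
  max <- as.numeric(max)
  if (length(names) < 1L) stop("an MMI space needs at least one axis")
  if (anyDuplicated(names)) stop("axis names must be unique")
  if (length(min) != length(names) || length(max) != length(names)) {
    stop("'min' and 'max' must have one entry per axis")
  }
  if (any(!is.finite(min)) || any(!is.finite(max))) {
    stop("axis bounds must be finite")
  }
  if (any(max <= min)) {
    bad <- names[max <= min]
    stop("degenerate axis (max <= min): ", paste(bad, collapse = ", "))
  }
  structure(
    data.frame(name = names, min = min, max = max,
               units = as.character(units), stringsAsFactors = FALSE),
    class = c("mmi_space", "data.frame")
  )
}

#' The published region of interest for the ectopic-beat study
#'
#' Four MMIs with their biophysically plausible ranges: initial diastolic
#' cytosolic calcium (100-300 nM), initial free sarcoplasmic-reticulum
#' calcium (300-700 uM), the inward-rectifier potassium conductance scaling
#' factor (0-1) and the ryanodine-receptor opening-rate scaling factor
#' (0.5-1.5).
#'
#' @return An [mmi_space] with axes `ca_i_ini`, `ca_sr_ini`, `g_k1_sf`,
#'   `k_ryr_sf`.
#' @export
default_mmi_space <- function() {
  mmi_space(
    names = c("ca_i_ini", "ca_sr_ini", "g_k1_sf", "k_ryr_sf"),
    min   = c(100, 300, 0,   0.5),
    max   = c(300, 700, 1,   1.5),
    units = c("nM", "uM", "dimensionless", "dimensionless")
  )
}

#' @export
print.mmi_space <- function(x, ...) {
  cat("MMI space with", nrow(x), "axes:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

space_dim <- function(space) nrow(space)

# Coerce a point (named numeric vector, unnamed numeric vector in axis order,
# data frame, or matrix) to a numeric matrix with one column per axis in
# space order.
as_point_matrix <- function(point, space) {
  nm <- space$name
  if (is.data.frame(point)) point <- as.matrix(point[, intersect(colnames(point), nm), drop = FALSE])
  if (is.null(dim(point))) {
    if (length(point) != length(nm)) {
      stop("point has ", length(point), " values; space has ", length(nm), " axes")
    }
    point <- matrix(point, nrow = 1L,
                    dimnames = list(NULL, names(point) %||% nm))
  }
  if (!is.null(colnames(point))) {
    missing <- setdiff(nm, colnames(point))
    if (length(missing)) {
      stop("point is missing axes: ", paste(missing, collapse = ", "))
    }
    point <- point[, nm, drop = FALSE]
  } else {
    if (ncol(point) != length(nm)) {
      stop("point matrix has ", ncol(point), " columns; space has ",
           length(nm), " axes")
    }
    colnames(point) <- nm
  }
  storage.mode(point) <- "double"
  point
}

#' Min-max scale MMI points to the unit hypercube of the space
#'
#' Applies `(x - min) / (max - min)` per axis. Points outside the region of
#' interest scale to values outside `[0, 1]`; no clipping is performed, so the
#' surrogate can be evaluated by extrapolation (required, e.g., when
#' propagating normal uncertainty centred on a boundary of the region).
#'
#' @param point a named numeric vector, data frame or matrix of points in
#'   native units.
#' @param space an [mmi_space].
#' @return A numeric matrix of scaled coordinates, one row per point, columns
#'   in axis order.
#' @examples
#' scale_mmi(c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.338,
#'             k_ryr_sf = 1), default_mmi_space())
#' @export
scale_mmi <- function(point, space) {
  x <- as_point_matrix(point, space)
  sweep(sweep(x, 2L, space$min, "-"), 2L, space$max - space$min, "/")
}

#' Invert min-max scaling back to native units
#'
#' Exact inverse of [scale_mmi] on the whole real line per axis.
#'
#' @param scaled a numeric vector or matrix of scaled coordinates.
#' @param space an [mmi_space].
#' @return A numeric matrix of native-unit coordinates.
#' @export
unscale_mmi <- function(scaled, space) {
  nm <- space$name
  if (is.null(dim(scaled))) {
    if (length(scaled) != length(nm)) {
      stop("scaled vector length ", length(scaled), " != space dimension ",
           length(nm))
    }
    scaled <- matrix(scaled, nrow = 1L, dimnames = list(NULL, names(scaled) %||% nm))
  }
  if (!is.null(colnames(scaled))) scaled <- scaled[, nm, drop = FALSE]
  colnames(scaled) <- nm
  sweep(sweep(scaled, 2L, space$max - space$min, "*"), 2L, space$min, "+")
}
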