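#' Define a square study area and its grid geometry
#'
#' The analysis operates on a square window (default 3 km x 3 km) centred on a
#' city centre, rasterised into `n_cells_per_side` x `n_cells_per_side` cells.
#' The kernel bandwidth used for density estimation is tied to the window:
#' `side / bandwidth_divisor`. With the defaults (side 3000 m, 150 cells,
#' divisor 40) this gives a 20 m cell and a 75 m bandwidth.
#'
#' @param centre_x,centre_y centre of the study area, planar metres.
#' @param side side length of the square window in metres (default 3000).
#' @param n_cells_per_side number of grid cells along each side (default 150).
#' @param bandwidth_divisor divisor applied to `side` to obtain the default
#'   KDE bandwidth (default 40).
#' @return an object of class `study_area` with derived fields `cell_size`
#'   and `kde_bandwidth`.
#' @examples
#' a <- study_area(0, 0)
#' a$cell_size      # 20
#' a$kde_bandwidth  # 75
#' @export
study_area <- function(centre_x = 0, centre_y = 0, side = 3000,
                       n_cells_per_side = 150, bandwidth_divisor = 40) {
  stopifnot(is.finite(centre_x), is.finite(centre_y), side > 0,
            n_cells_per_side >= 1, bandwidth_divisor > 0)
  structure(list(
    centre_x = centre_x, centre_y = centre_y, side = side,
    n_cells_per_side = as.integer(n_cells_per_side),
    bandwidth_divisor = bandwidth_divisor,
    cell_size = side / n_cells_per_side,
    kde_bandwidth = side / bandwidth_divisor
  ), class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf(
    "study_area: %g m x %g m centred at (%g, %g)\n  %d x %d cells of %g m, kde bandwidth %g m\n",
    x$side, x$side, x$centre_x, x$centre_y,
    x$n_cells_per_side, x$n_cells_per_side, x$cell_size, x$kde_bandwidth))
  invisible(x)
}

#' Construct a labelled planar point set
#'
#' A `point_set` is the basic container for one class of points: the POIs of a
#' single class, or crime incidents (label `"crime"`). Duplicate coordinates
#' are permitted and meaningful: the open-data anonymisation step snaps many
#' incidents onto identical points, and kernel density estimation handles the
#' multiplicity naturally.
#'
#' @param x,y coordinate vectors in planar metres; must be finite.
#' @param label class name, or `"crime"`.
#' @return object of class `point_set` with fields `label`, `x`, `y`.
#' @export
point_set <- function(x = numeric(), y = numeric(), label = "points") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_poicrime("point_set: x and y lengths differ")
  }
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y)))) {
    stop_poicrime("point_set: non-finite coordinates")
  }
  structure(list(label = label, x = x, y = y), class = "point_set")
}

#' @export
length.point_set <- function(x) length(x$x)

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set '%s': %d points\n", x$label, length(x)))
  invisible(x)
}

#' Clip a point set to a (padded) study window
#'
#' Keeps the points lying inside the axis-aligned square of side
#' `area$side + 2 * pad` centred on the area centre. Padding equal to the KDE
#' bandwidth is applied before density estimation so that points just outside
#' the study area still contribute mass inside it (no border artefacts).
#'
#' The window test is half-open: a point exactly on the minimum edge is kept,
#' one exactly on the maximum edge is dropped. This prevents double counting
#' when windows tile the plane and makes the operation idempotent.
#'
#' @param points a [point_set()].
#' @param area a [study_area()].
#' @param pad padding in metres, `>= 0` (typically the kernel bandwidth).
#' @return a `point_set` with the retained points, label preserved.
#' @export
window_points <- function(points, area, pad = 0) {
  stopifnot(inherits(points, "point_set"), inherits(area, "study_area"), pad >= 0)
  half <- area$side / 2 + pad
  xmin <- area$centre_x - half; xmax <- area$centre_x + half
  ymin <- area$centre_y - half; ymax <- area$centre_y + half
  keep <- points$x >= xmin & points$x < xmax & points$y >= ymin & points$y < ymax
  point_set(points$x[keep], points$y[keep], label = points$label)
}

#' Cell-centre sample coordinates of the study grid
#'
#' Returns the `n_cells_per_side^2` cell-centre coordinates at which all
#' densities are sampled, in row-major order: the row index increases with y,
#' the column index with x, and x varies fastest. This flattening order is the
#' contract that keeps basis-matrix columns and flattened crime vectors
#' aligned; [estimate_density()] and [build_basis()] use the same order.
#'
#' Cell centres sit at `min + (i + 0.5) * cell_size` for `i = 0, ...,
#' n_cells_per_side - 1` along each axis.
#'
#' @param area a [study_area()].
#' @return data.frame with columns `x`, `y` and `n_cells_per_side^2` rows.
#' @export
grid_geometry <- function(area) {
  stopifnot(inherits(area, "study_area"))
  n <- area$n_cells_per_side
  cs <- area$cell_size
  xmin <- area$centre_x - area$side / 2
  ymin <- area$centre_y - area$side / 2
  ax <- xmin + (seq_len(n) - 0.5) * cs
  ay <- ymin + (seq_len(n) - 0.5) * cs
  data.frame(x = rep(ax, times = n), y = rep(ay, each = n))
}

## Row-major flattening of a grid-valued matrix values[iy, ix] (y in rows,
## x in columns) into the order produced by grid_geometry().
flatten_grid <- function(values) as.vector(t(values))

## Inverse of flatten_grid for an n x n grid.
unflatten_grid <- function(v, n) matrix(v, nrow = n, ncol = n, byrow = TRUE)
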