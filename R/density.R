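#' Kernel density estimate of a point set over the study grid
#'
#' Evaluates, at every cell centre of the study grid, the two-dimensional
#' kernel density estimate
#' \deqn{F(x) = \frac{1}{n} \sum_{i=1}^{n} c(h)\, k(\|x - p_i\| / h),}
#' where `k` is the kernel shape, `c(h)` its planar normalising constant and
#' `n` the number of points. Values are reported in points per square
#' kilometre; with the `1/n` normalisation the grid integrates to (about) one
#' point, i.e. it is a probability density over the plane expressed per km^2.
#'
#' Callers should window the input with padding equal to the bandwidth
#' ([window_points()]) so that points just outside the study square still
#' contribute: this is what removes border artefacts.
#'
#' @param points a [point_set()]; may be empty (all-zero grid, with warning).
#' @param area a [study_area()].
#' @param kernel a [kernel_spec()].
#' @param scale_factor inverse sampling fraction recorded with the grid when
#'   the points are a subsample (e.g. 2 for one half of a 2-fold split); used
#'   by [rate_values()] to put densities from different subsamples on the
#'   full-data incident-rate scale. Does not change the stored values.
#' @return object of class `density_grid`: fields `values` (matrix, rows =
#'   increasing y, columns = increasing x; per km^2), `area`, `kernel`,
#'   `source_label`, `n_source_points`, `scale_factor`.
#' @export
estimate_density <- function(points, area, kernel, scale_factor = 1) {
  stopifnot(inherits(points, "point_set"), inherits(area, "study_area"),
            inherits(kernel, "kernel_spec"))
  n_cells <- area$n_cells_per_side
  cs <- area$cell_size
  xmin <- area$centre_x - area$side / 2
  ymin <- area$centre_y - area$side / 2
  ax <- xmin + (seq_len(n_cells) - 0.5) * cs
  ay <- ymin + (seq_len(n_cells) - 0.5) * cs
  vals <- matrix(0, nrow = n_cells, ncol = n_cells) # [iy, ix]
  n <- length(points)
  if (n == 0L) {
    warning("estimate_density: empty point set '", points$label,
            "', returning all-zero grid")
  } else {
    cutoff <- kernel_cutoff(kernel)
    cnorm <- kernel_norm_const(kernel$kind, kernel$bandwidth)
    h <- kernel$bandwidth
    for (i in seq_len(n)) {
      px <- points$x[i]; py <- points$y[i]
      ix <- which(abs(ax - px) <= cutoff)
      iy <- which(abs(ay - py) <= cutoff)
      if (!length(ix) || !length(iy)) next
      d <- sqrt(outer((ay[iy] - py)^2, (ax[ix] - px)^2, `+`))
      vals[iy, ix] <- vals[iy, ix] + cnorm * kernel_shape(kernel$kind, d / h)
    }
    vals <- vals / n
  }
  structure(list(
    values = vals * 1e6, # m^-2 -> km^-2
    area = area, kernel = kernel,
    source_label = points$label,
    n_source_points = n,
    scale_factor = scale_factor
  ), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density_grid '%s': %d x %d cells, %d source points, max %.3g per km^2\n",
    x$source_label, nrow(x$values), ncol(x$values), x$n_source_points,
    max(x$values)))
  invisible(x)
}

#' Flatten a density grid into the canonical sample order
#'
#' Row-major order, matching [grid_geometry()]: x varies fastest, y slowest.
#'
#' @param grid a `density_grid`.
#' @return numeric vector of length `n_cells_per_side^2`.
#' @export
flatten_density <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  flatten_grid(grid$values)
}

#' Flattened density on the full-data incident-rate scale
#'
#' Converts the per-point (probability) density to an incident-rate density by
#' multiplying by the source point count and by the grid's recorded inverse
#' sampling fraction, so that densities estimated from different random
#' subsamples of the same data are directly comparable (incidents per km^2 of
#' the full data).
#'
#' @param grid a `density_grid`.
#' @return numeric vector, same order as [flatten_density()].
#' @export
rate_values <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  flatten_grid(grid$values) * grid$n_source_points * grid$scale_factor
}

#' Build the basis matrix of per-class density maps
#'
#' Estimates one density grid per POI class and stacks their row-major
#' flattenings as columns: column j of the result is the vectorised density
#' map of class j. This is the regressor matrix of the sparse crime-density
#' model. The column order follows the order of `class_sets`.
#'
#' @param class_sets list of [point_set()]s, one per POI class (the caller
#'   fixes the order); empty sets give all-zero columns.
#' @param area a [study_area()].
#' @param kernel a [kernel_spec()].
#' @param scale_factor passed to [estimate_density()] for every class.
#' @param rate if `TRUE` columns are on the incident-rate scale
#'   ([rate_values()]); if `FALSE` (default) on the per-point density scale.
#' @return object of class `basis_matrix`: fields `matrix`
#'   (`n_cells^2 x n_classes`), `columns` (class names), `area`, `kernel`.
#' @export
build_basis <- function(class_sets, area, kernel, scale_factor = 1,
                        rate = FALSE) {
  stopifnot(is.list(class_sets), length(class_sets) >= 1)
  labels <- vapply(class_sets, function(p) p$label, character(1))
  cols <- lapply(class_sets, function(p) {
    g <- withCallingHandlers(
      estimate_density(p, area, kernel, scale_factor = scale_factor),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(p) == 0L) {
      warning("build_basis: class '", p$label, "' has no points; zero column")
    }
    if (rate) rate_values(g) else flatten_density(g)
  })
  structure(list(
    matrix = do.call(cbind, cols),
    columns = labels,
    area = area, kernel = kernel
  ), class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("basis_matrix: %d samples x %d classes (%s kernel, h = %g m)\n",
              nrow(x$matrix), ncol(x$matrix), x$kernel$kind,
              x$kernel$bandwidth))
  invisible(x)
}

#' Write / read a density grid as a headered CSV raster
#'
#' The header records the grid geometry and provenance as `#key=value`
#' comment lines, followed by the value matrix (rows = increasing y). The
#' round trip restores the grid exactly (values to full double precision via
#' 17 significant digits).
#'
#' @param grid a `density_grid`.
#' @param path file path.
#' @return `write_density_csv` returns `path` invisibly;
#'   `read_density_csv` returns a `density_grid`.
#' @export
write_density_csv <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  a <- grid$area
  hdr <- c(
    sprintf("#source_label=%s", grid$source_label),
    sprintf("#n_source_points=%d", grid$n_source_points),
    sprintf("#scale_factor=%.17g", grid$scale_factor),
    sprintf("#centre_x=%.17g", a$centre_x),
    sprintf("#centre_y=%.17g", a$centre_y),
    sprintf("#side=%.17g", a$side),
    sprintf("#n_cells_per_side=%d", a$n_cells_per_side),
    sprintf("#bandwidth_divisor=%.17g", a$bandwidth_divisor),
    sprintf("#kernel=%s", grid$kernel$kind),
    sprintf("#bandwidth=%.17g", grid$kernel$bandwidth)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    format(grid$values, digits = 17, scientific = TRUE, trim = TRUE),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr_lines), "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1))
  area <- study_area(
    centre_x = as.numeric(meta$centre_x), centre_y = as.numeric(meta$centre_y),
    side = as.numeric(meta$side),
    n_cells_per_side = as.integer(meta$n_cells_per_side),
    bandwidth_divisor = as.numeric(meta$bandwidth_divisor))
  vals <- as.matrix(utils::read.csv(
    textConnection(lines[!grepl("^#", lines)]), header = FALSE))
  dimnames(vals) <- NULL
  structure(list(
    values = vals, area = area,
    kernel = kernel_spec(meta$kernel, as.numeric(meta$bandwidth)),
    source_label = meta$source_label,
    n_source_points = as.integer(meta$n_source_points),
    scale_factor = as.numeric(meta$scale_factor)
  ), class = "density_grid")
}

#' Heat-map plot of a density grid
#'
#' @param x a `density_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_grid <- function(x, ...) {
  a <- x$area
  n <- a$n_cells_per_side
  ax <- a$centre_x - a$side / 2 + (seq_len(n) - 0.5) * a$cell_size
  ay <- a$centre_y - a$side / 2 + (seq_len(n) - 0.5) * a$cell_size
  graphics::image(ax, ay, t(x$values), xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("%s density (per km^2)", x$source_label),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
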