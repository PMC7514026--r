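## Shared fixtures, all generated in code at test time.

small_area <- function(side = 600, n = 30) {
  study_area(0, 0, side = side, n_cells_per_side = n)
}

## Brute-force KDE oracle: plain double loop over grid samples and points,
## independent of the gridded estimator's pruning and accumulation order.
naive_kde <- function(points, area, kernel) {
  g <- grid_geometry(area)
  vapply(seq_len(nrow(g)), function(i) {
    mean(kernel_profile(
      kernel, sqrt((g$x[i] - points$x)^2 + (g$y[i] - points$y)^2)))
  }, numeric(1)) * 1e6
}

SIGNAL_CLASSES <- c("Pubs, Bars and Inns", "Fast Food and Takeaway Outlets",
                    "Bus Stops")

## Three signal classes plus 17 clutter classes at a coarse grid: the
## standard selection fixture (memoised; several tests share it).
.fixture_cache <- new.env(parent = emptyenv())
selection_fixture <- function(seed = 401, n_cells = 40) {
  key <- paste0("fx", seed, "_", n_cells)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- benchmark_city_spec(seed, n_cells_per_side = n_cells,
                              n_crimes = 1500, n_clutter = 17)
  bundle <- generate_city(spec)
  kern <- spec$kernel
  basis <- suppressWarnings(
    build_basis(bundle$class_sets, bundle$area, kern, rate = TRUE))
  y <- rate_values(suppressWarnings(
    estimate_density(bundle$crimes, bundle$area, kern)))
  .fixture_cache[[key]] <- list(spec = spec, bundle = bundle, basis = basis,
                                y = y, kernel = kern)
  .fixture_cache[[key]]
}

## Crime CSV fixture in the open-police-data dialect with planar coordinates
## (crs = "none") so reader tests are independent of the projection.
write_crime_fixture <- function(path, lon, lat, crime_type,
                                month = "2024-06") {
  n <- length(lon)
  df <- data.frame(
    `Crime ID` = sprintf("id%03d", seq_len(n)),
    `Month` = rep(month, n),
    `Reported by` = rep("Test Force", n),
    `Falls within` = rep("Test Force", n),
    `Longitude` = lon, `Latitude` = lat,
    `LSOA code` = rep("W01000001", n),
    `LSOA name` = rep("Test 001", n),
    `Crime type` = crime_type,
    `Last outcome category` = rep("Under investigation", n),
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
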