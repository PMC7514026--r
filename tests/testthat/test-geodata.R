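test_that("study area derives cell size and bandwidth from its divisors", {
  a <- study_area(0, 0)
  expect_equal(a$cell_size, 20)
  expect_equal(a$kde_bandwidth, 75)
  b <- study_area(1000, -500, side = 1200, n_cells_per_side = 60,
                  bandwidth_divisor = 30)
  expect_equal(b$cell_size, 20)
  expect_equal(b$kde_bandwidth, 40)
})

test_that("grid geometry has n^2 cell-centre samples in row-major order", {
  a <- study_area(100, 200, side = 40, n_cells_per_side = 4)
  g <- grid_geometry(a)
  expect_equal(nrow(g), 16)
  ## x varies fastest, y slowest; centres at min + (i + 0.5) * cell
  expect_equal(g$x[1:4], c(85, 95, 105, 115))
  expect_equal(g$y[1:4], rep(185, 4))
  expect_equal(g$y[5], 195)
  ## single-cell grid samples the area centre
  g1 <- grid_geometry(study_area(7, -3, side = 10, n_cells_per_side = 1))
  expect_equal(unlist(g1), c(x = 7, y = -3))
  ## count invariant across a few geometries
  for (n in c(2, 7, 30)) {
    expect_equal(nrow(grid_geometry(study_area(0, 0, 900, n))), n^2)
  }
})

test_that("windowing keeps the padded square with half-open edges", {
  a <- study_area(0, 0, side = 1000, n_cells_per_side = 10)
  p <- point_set(c(0, 500 + 75 + 1, -575, 575, 0), c(0, 0, 0, 0, -575),
                 label = "t")
  w <- window_points(p, a, pad = 75)
  ## centre kept; beyond half+pad dropped; exactly on min edge kept,
  ## on max edge dropped
  expect_equal(w$x, c(0, -575, 0))
  expect_equal(w$y, c(0, 0, -575))
  ## idempotence
  w2 <- window_points(w, a, pad = 75)
  expect_identical(w2$x, w$x)
  expect_identical(w2$y, w$y)
})

test_that("uniform points over a doubled square survive windowing at rate ~1/4", {
  a <- study_area(0, 0, side = 1000, n_cells_per_side = 10)
  p <- withr::with_seed(11, point_set(runif(1000, -1000, 1000),
                                      runif(1000, -1000, 1000), "u"))
  frac <- length(window_points(p, a, pad = 0)) / 1000
  ## binomial sd at p = 1/4, n = 1000 is 0.0137; 4.5 sd band
  expect_lt(abs(frac - 0.25), 0.062)
})

test_that("crime reader filters by type and drops unparseable coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_crime_fixture(f, lon = c(10, 20, 30), lat = c(1, 2, 3),
                      crime_type = c("Violence and sexual offences",
                                     "Robbery", "Burglary"))
  one <- read_crime_table(f, crime_type_filter = "Violence and sexual offences",
                          crs = "none")
  expect_equal(nrow(one), 1)
  expect_equal(one$x, 10)
  all_types <- read_crime_table(f, crime_type_filter = c(
    "Violence and sexual offences", "Robbery", "Burglary"), crs = "none")
  expect_equal(nrow(all_types), 3)
  ## blank longitude: record dropped and counted
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_crime_fixture(f2, lon = "", lat = 3,
                      crime_type = "Violence and sexual offences")
  none <- read_crime_table(f2, crs = "none")
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_dropped"), 1L)
})

test_that("crime reader reports missing columns and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Crime ID,Month,Longitude", "a,2024-01,1.0"), f)
  err <- expect_error(read_crime_table(f), class = "poicrime_schema_error")
  expect_match(conditionMessage(err), "latitude")
  expect_match(conditionMessage(err), "crime type")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_crime_fixture(f2, lon = numeric(), lat = numeric(),
                      crime_type = character())
  expect_warning(empty <- read_crime_table(f2, crs = "none"), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("filtering commutes with parsing", {
  f <- withr::local_tempfile(fileext = ".csv")
  types <- rep(c("Violence and sexual offences", "Robbery", "Drugs"), 4)
  write_crime_fixture(f, lon = seq_len(12), lat = seq_len(12),
                      crime_type = types)
  permissive <- read_crime_table(f, crime_type_filter = unique(types),
                                 crs = "none")
  manual <- permissive[
    permissive$crime_type == "Violence and sexual offences", ]
  rownames(manual) <- NULL
  direct <- read_crime_table(f, crs = "none")
  attr(manual, "n_dropped") <- attr(direct, "n_dropped")
  expect_equal(direct, manual)
})

test_that("poi reader returns records plus a consistent hierarchy", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    Name = paste("venue", 1:5),
    Class = c("Pubs, Bars and Inns", "Pubs, Bars and Inns", "Cafes",
              "Cafes", "Cafes"),
    Category = "Eating and Drinking", Group = "Retail",
    Easting = c(1, 2, 3, 3, 5), Northing = c(9, 8, 7, 7, 5))
  utils::write.csv(df, f, row.names = FALSE)
  out <- read_poi_table(f)
  expect_equal(nrow(out$records), 5) # duplicates retained
  expect_equal(nrow(out$hierarchy), 2)
  ## round trip: writing the class sets back reproduces the hierarchy
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_poi_csv(poi_class_sets(out$records), f2, hierarchy = out$hierarchy)
  out2 <- read_poi_table(f2)
  expect_equal(out2$hierarchy[order(out2$hierarchy$class_name), ],
               out$hierarchy[order(out$hierarchy$class_name), ],
               ignore_attr = TRUE)

  ## a class in two categories is a consistency error naming the offender
  df$Category[3] <- "Shopping"
  utils::write.csv(df, f, row.names = FALSE)
  err <- expect_error(read_poi_table(f), class = "poicrime_hierarchy_error")
  expect_match(conditionMessage(err), "Cafes")
})

test_that("poi reader handles an empty file", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("Name,Class,Category,Group,Easting,Northing", f)
  out <- read_poi_table(f)
  expect_equal(nrow(out$records), 0)
  expect_equal(nrow(out$hierarchy), 0)
})

test_that("transverse Mercator core reproduces the published worked example", {
  ## canonical National Grid example: 52d39'27.2531"N 1d43'4.5177"E (Airy)
  lat <- (52 + 39 / 60 + 27.2531 / 3600) * pi / 180
  lon <- (1 + 43 / 60 + 4.5177 / 3600) * pi / 180
  p <- poicrime:::tm_project(lon, lat, poicrime:::ELL_AIRY)
  expect_equal(p$x, 651409.903, tolerance = 1e-8)
  expect_equal(p$y, 313177.270, tolerance = 1e-8)
})

test_that("projection preserves local distances and round-trips", {
  skip_if_not_installed("geosphere")
  ll1 <- c(-3.18, 51.48); ll2 <- c(-3.17, 51.485)
  p <- lonlat_to_planar(c(ll1[1], ll2[1]), c(ll1[2], ll2[2]))
  d_planar <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  d_geo <- geosphere::distGeo(ll1, ll2)
  ## grid distances carry the projection scale factor (~4e-4 here)
  expect_lt(abs(d_planar - d_geo) / d_geo, 1e-3)
  back <- planar_to_lonlat(p$x, p$y)
  ## round trip to ~1e-7 degrees (about a centimetre)
  expect_equal(back$lon, c(ll1[1], ll2[1]), tolerance = 1e-7)
  expect_equal(back$lat, c(ll1[2], ll2[2]), tolerance = 1e-7)
})
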