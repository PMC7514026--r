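## Planar projection of WGS84 longitude/latitude.
##
## Open police extracts carry WGS84 lon/lat, while all internal computation is
## in planar metres (Euclidean distances are only meaningful in a metric
## projection). The default CRS reproduces British National Grid semantics:
## a Helmert datum shift from WGS84 to OSGB36 (Airy 1830 ellipsoid) followed
## by the National Grid transverse Mercator projection. The Helmert shift is
## the standard 7-parameter approximation (accurate to a few metres, far
## below the tens-of-metres anonymisation noise in the data). A "none" CRS is
## also available for files that already carry planar metres.

ELL_WGS84 <- list(a = 6378137.0, b = 6356752.314245)
ELL_AIRY  <- list(a = 6377563.396, b = 6356256.909)

## National Grid projection constants: scale on central meridian, true origin
## at 49N 2W, false easting/northing 400000 / -100000.
OSGB_F0   <- 0.9996012717
OSGB_LAT0 <- 49 * pi / 180
OSGB_LON0 <- -2 * pi / 180
OSGB_E0   <- 400000
OSGB_N0   <- -100000

## 7-parameter Helmert transformation WGS84 -> OSGB36 (tx, ty, tz metres;
## s in ppm; rx, ry, rz in arc-seconds).
HELMERT_WGS84_TO_OSGB36 <- c(
  tx = -446.448, ty = 125.157, tz = -542.060,
  s = 20.4894, rx = -0.1502, ry = -0.2470, rz = -0.8421
)

geodetic_to_cartesian <- function(lon, lat, ell) {
  e2 <- 1 - (ell$b / ell$a)^2
  nu <- ell$a / sqrt(1 - e2 * sin(lat)^2)
  list(x = nu * cos(lat) * cos(lon),
       y = nu * cos(lat) * sin(lon),
       z = nu * (1 - e2) * sin(lat))
}

cartesian_to_geodetic <- function(x, y, z, ell) {
  e2 <- 1 - (ell$b / ell$a)^2
  p <- sqrt(x^2 + y^2)
  lat <- atan2(z, p * (1 - e2))
  for (i in 1:8) { # converges to < 1e-12 rad in a few iterations
    nu <- ell$a / sqrt(1 - e2 * sin(lat)^2)
    lat <- atan2(z + e2 * nu * sin(lat), p)
  }
  list(lon = atan2(y, x), lat = lat)
}

helmert_apply <- function(x, y, z, h, invert = FALSE) {
  sgn <- if (invert) -1 else 1
  s <- 1 + sgn * h[["s"]] * 1e-6
  as_rad <- pi / (180 * 3600)
  rx <- sgn * h[["rx"]] * as_rad
  ry <- sgn * h[["ry"]] * as_rad
  rz <- sgn * h[["rz"]] * as_rad
  list(
    x = sgn * h[["tx"]] + s * x - rz * y + ry * z,
    y = sgn * h[["ty"]] + rz * x + s * y - rx * z,
    z = sgn * h[["tz"]] - ry * x + rx * y + s * z
  )
}

## Meridional arc (Airy ellipsoid), standard National Grid series.
tm_meridional_arc <- function(lat, ell, f0) {
  a <- ell$a; b <- ell$b
  n <- (a - b) / (a + b)
  dl <- lat - OSGB_LAT0; sl <- lat + OSGB_LAT0
  b * f0 * (
    (1 + n + 5 / 4 * n^2 + 5 / 4 * n^3) * dl -
      (3 * n + 3 * n^2 + 21 / 8 * n^3) * sin(dl) * cos(sl) +
      (15 / 8 * (n^2 + n^3)) * sin(2 * dl) * cos(2 * sl) -
      (35 / 24 * n^3) * sin(3 * dl) * cos(3 * sl)
  )
}

tm_project <- function(lon, lat, ell) {
  a <- ell$a; f0 <- OSGB_F0
  e2 <- 1 - (ell$b / a)^2
  sl <- sin(lat); cl <- cos(lat); tl <- tan(lat)
  nu <- a * f0 / sqrt(1 - e2 * sl^2)
  rho <- a * f0 * (1 - e2) * (1 - e2 * sl^2)^(-1.5)
  eta2 <- nu / rho - 1
  M <- tm_meridional_arc(lat, ell, f0)
  I <- M + OSGB_N0
  II <- nu / 2 * sl * cl
  III <- nu / 24 * sl * cl^3 * (5 - tl^2 + 9 * eta2)
  IIIA <- nu / 720 * sl * cl^5 * (61 - 58 * tl^2 + tl^4)
  IV <- nu * cl
  V <- nu / 6 * cl^3 * (nu / rho - tl^2)
  VI <- nu / 120 * cl^5 * (5 - 18 * tl^2 + tl^4 + 14 * eta2 - 58 * tl^2 * eta2)
  dl <- lon - OSGB_LON0
  list(
    x = OSGB_E0 + IV * dl + V * dl^3 + VI * dl^5,
    y = I + II * dl^2 + III * dl^4 + IIIA * dl^6
  )
}

tm_unproject <- function(E, N, ell) {
  a <- ell$a; f0 <- OSGB_F0
  e2 <- 1 - (ell$b / a)^2
  lat <- OSGB_LAT0 + (N - OSGB_N0) / (a * f0)
  repeat {
    M <- tm_meridional_arc(lat, ell, f0)
    dN <- N - OSGB_N0 - M
    if (all(abs(dN) < 1e-5)) break
    lat <- lat + dN / (a * f0)
  }
  sl <- sin(lat); tl <- tan(lat); secl <- 1 / cos(lat)
  nu <- a * f0 / sqrt(1 - e2 * sl^2)
  rho <- a * f0 * (1 - e2) * (1 - e2 * sl^2)^(-1.5)
  eta2 <- nu / rho - 1
  VII <- tl / (2 * rho * nu)
  VIII <- tl / (24 * rho * nu^3) * (5 + 3 * tl^2 + eta2 - 9 * tl^2 * eta2)
  IX <- tl / (720 * rho * nu^5) * (61 + 90 * tl^2 + 45 * tl^4)
  X <- secl / nu
  XI <- secl / (6 * nu^3) * (nu / rho + 2 * tl^2)
  XII <- secl / (120 * nu^5) * (5 + 28 * tl^2 + 24 * tl^4)
  XIIA <- secl / (5040 * nu^7) * (61 + 662 * tl^2 + 1320 * tl^4 + 720 * tl^6)
  dE <- E - OSGB_E0
  list(
    lat = lat - VII * dE^2 + VIII * dE^4 - IX * dE^6,
    lon = OSGB_LON0 + X * dE - XI * dE^3 + XII * dE^5 - XIIA * dE^7
  )
}

#' Project WGS84 longitude/latitude to planar metres
#'
#' @param lon,lat numeric vectors of WGS84 coordinates in degrees.
#' @param crs `"bng"` (default) for British National Grid semantics (Helmert
#'   datum shift to OSGB36 then transverse Mercator), or `"none"` to pass the
#'   inputs through unchanged (inputs already planar metres).
#' @return list with numeric vectors `x` (easting) and `y` (northing), metres.
#' @seealso [planar_to_lonlat()] for the inverse.
#' @export
lonlat_to_planar <- function(lon, lat, crs = "bng") {
  if (crs == "none") return(list(x = as.numeric(lon), y = as.numeric(lat)))
  if (crs != "bng") stop_poicrime("unknown crs: ", crs)
  lonr <- lon * pi / 180; latr <- lat * pi / 180
  c1 <- geodetic_to_cartesian(lonr, latr, ELL_WGS84)
  c2 <- helmert_apply(c1$x, c1$y, c1$z, HELMERT_WGS84_TO_OSGB36)
  g <- cartesian_to_geodetic(c2$x, c2$y, c2$z, ELL_AIRY)
  tm_project(g$lon, g$lat, ELL_AIRY)
}

#' Inverse projection: planar metres to WGS84 longitude/latitude
#'
#' @param x,y easting/northing in metres.
#' @param crs as in [lonlat_to_planar()].
#' @return list with numeric vectors `lon`, `lat` in degrees.
#' @export
planar_to_lonlat <- function(x, y, crs = "bng") {
  if (crs == "none") return(list(lon = as.numeric(x), lat = as.numeric(y)))
  if (crs != "bng") stop_poicrime("unknown crs: ", crs)
  g <- tm_unproject(x, y, ELL_AIRY)
  c1 <- geodetic_to_cartesian(g$lon, g$lat, ELL_AIRY)
  c2 <- helmert_apply(c1$x, c1$y, c1$z, HELMERT_WGS84_TO_OSGB36, invert = TRUE)
  w <- cartesian_to_geodetic(c2$x, c2$y, c2$z, ELL_WGS84)
  list(lon = w$lon * 180 / pi, lat = w$lat * 180 / pi)
}
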