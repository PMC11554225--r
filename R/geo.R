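#' WGS84 geodesic distance in kilometres
#'
#' Ellipsoidal (WGS84) distance between two points, in kilometres. A thin
#' wrapper over [geosphere::distGeo()] so that all distance computations in
#' the package go through a single, vectorized entry point.
#'
#' @param lat1,lon1 Start coordinates, decimal degrees.
#' @param lat2,lon2 End coordinates, decimal degrees.
#' @return Numeric vector of distances in km; non-negative, symmetric, and
#'   zero exactly for identical points.
#' @examples
#' geodesic_km(0, 0, 0, 1)  # one degree of longitude on the equator
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  d <- geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
  # distGeo returns exact 0 for identical points; guard tiny negatives anyway
  pmax(d, 0)
}

#' Minimal signed heading change
#'
#' Signed angular difference `c2 - c1` wrapped to `(-180, 180]`. Course over
#' ground lives on a circle; naive subtraction across the 0/360 seam invents
#' 350-degree turns where the vessel turned 10 degrees.
#'
#' @param c1,c2 Courses in degrees, `[0, 360)`.
#' @return Signed change in degrees, in `(-180, 180]`.
#' @examples
#' heading_change(350, 10)  # +20, not -340
#' @export
heading_change <- function(c1, c2) {
  d <- (c2 - c1) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Unwrap a course sequence to a continuous angle
#'
#' Converts a sequence of compass courses in `[0, 360)` into a continuous
#' angle sequence (successive differences are minimal signed changes), so
#' that linear interpolation does not jump across the 0/360 seam.
#'
#' @param cog Numeric vector of courses in degrees.
#' @return Numeric vector, same length; `unwrap_heading(x) %% 360 == x`.
#' @keywords internal
unwrap_heading <- function(cog) {
  if (length(cog) < 2L) return(cog)
  cog[1] + c(0, cumsum(heading_change(cog[-length(cog)], cog[-1])))
}

#' UTM zone of a longitude
#' @param lon Longitude in decimal degrees.
#' @return Integer zone number 1-60.
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Define a UTM projection
#'
#' Transverse Mercator parameters for a UTM zone (WGS84, k0 = 0.9996,
#' 500 km false easting). Used as the metric CRS of exposure grids; the
#' default grid takes the zone of the study-area centroid.
#'
#' @param zone UTM zone number (1-60).
#' @param north Logical; northern hemisphere (default `TRUE`).
#' @return An object of class `"utm_proj"`.
#' @export
utm_proj <- function(zone, north = TRUE) {
  stopifnot(zone >= 1, zone <= 60)
  structure(
    list(zone = as.integer(zone), north = north,
         lon0 = -183 + 6 * zone, k0 = 0.9996,
         x0 = 500000, y0 = if (north) 0 else 1e7),
    class = "utm_proj"
  )
}

#' @export
print.utm_proj <- function(x, ...) {
  cat(sprintf("UTM zone %d%s (WGS84), central meridian %d\n",
              x$zone, if (x$north) "N" else "S", x$lon0))
  invisible(x)
}

#' Project longitude/latitude to UTM metres
#'
#' Forward transverse Mercator projection on the WGS84 ellipsoid using the
#' Krueger series in the transverse Mercator conformal latitude (third
#' flattening expansion, terms through n^3; sub-millimetre within a zone).
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param proj A `"utm_proj"` object from [utm_proj()].
#' @return A two-column matrix with columns `x` (easting) and `y` (northing),
#'   metres.
#' @export
project_utm <- function(lon, lat, proj) {
  stopifnot(inherits(proj, "utm_proj"))
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64)
  al <- c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16,
          13 * n^2 / 48 - 3 * n^3 / 5,
          61 * n^3 / 240)
  phi <- lat * pi / 180
  dlam <- (lon - proj$lon0) * pi / 180
  es <- 2 * sqrt(n) / (1 + n)
  t <- sinh(atanh(sin(phi)) - es * atanh(es * sin(phi)))
  xi0 <- atan2(t, cos(dlam))
  eta0 <- atanh(sin(dlam) / sqrt(1 + t^2))
  xi <- xi0
  eta <- eta0
  for (j in 1:3) {
    xi <- xi + al[j] * sin(2 * j * xi0) * cosh(2 * j * eta0)
    eta <- eta + al[j] * cos(2 * j * xi0) * sinh(2 * j * eta0)
  }
  cbind(x = proj$x0 + proj$k0 * A * eta,
        y = proj$y0 + proj$k0 * A * xi)
}

#' Project points with a grid's CRS
#'
#' Helper dispatching on the projection stored in a grid spec: `NULL` means
#' the grid is already in the input coordinate units (e.g. a bathymetry grid
#' in degrees).
#' @keywords internal
project_points <- function(lon, lat, proj) {
  if (is.null(proj)) return(cbind(x = lon, y = lat))
  project_utm(lon, lat, proj)
}
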