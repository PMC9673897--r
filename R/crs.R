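# Coordinate handling.
#
# Two CRS families are supported:
#   * "geographic" - longitude/latitude in decimal degrees (WGS84);
#   * "local"      - a metric plane (metres) anchored at a reference
#                    longitude/latitude, as produced by the synthetic
#                    generator.
# Per-extent metric work on geographic data is done in an azimuthal
# equidistant projection centred on the working geometry, using the Gaussian
# radius of curvature at the centre latitude so planar areas track geodesic
# (ellipsoidal) areas closely over city-sized windows.

WGS84_A  <- 6378137
WGS84_F  <- 1 / 298.257223563
WGS84_E2 <- WGS84_F * (2 - WGS84_F)

#' Construct a coordinate reference descriptor
#'
#' @param type `"geographic"` (lon/lat degrees) or `"local"` (metres on a
#'   plane anchored at `lon0`, `lat0`).
#' @param lon0,lat0 anchor of a local metric plane (required for
#'   `type = "local"`; ignored otherwise).
#' @return an object of class `sdi_crs`.
#' @export
sdi_crs <- function(type = c("geographic", "local"), lon0 = NA_real_, lat0 = NA_real_) {
  type <- match.arg(type)
  if (type == "local" && (is.na(lon0) || is.na(lat0)))
    stop("a local CRS needs an anchor (lon0, lat0)")
  structure(list(type = type, lon0 = lon0, lat0 = lat0), class = "sdi_crs")
}

is_geographic <- function(crs) {
  inherits(crs, "sdi_crs") && crs$type == "geographic"
}

crs_equal <- function(a, b) {
  identical(a$type, b$type) &&
    (a$type == "geographic" || (isTRUE(all.equal(a$lon0, b$lon0)) &&
                                  isTRUE(all.equal(a$lat0, b$lat0))))
}

# Gaussian radius of curvature sqrt(M * N) at latitude phi (radians)
gaussian_radius <- function(phi) {
  s2 <- sin(phi)^2
  m <- WGS84_A * (1 - WGS84_E2) / (1 - WGS84_E2 * s2)^1.5
  n <- WGS84_A / sqrt(1 - WGS84_E2 * s2)
  sqrt(m * n)
}

# Azimuthal equidistant projection centred at (lon0, lat0), both in degrees.
# Returns fwd(lon, lat) -> list(x, y) metres and inv(x, y) -> list(lon, lat).
aeqd_projection <- function(lon0, lat0) {
  rad <- pi / 180
  l0 <- lon0 * rad; p0 <- lat0 * rad
  R <- gaussian_radius(p0)
  sp0 <- sin(p0); cp0 <- cos(p0)
  fwd <- function(lon, lat) {
    l <- lon * rad; p <- lat * rad
    dl <- l - l0
    cosc <- pmin(1, pmax(-1, sp0 * sin(p) + cp0 * cos(p) * cos(dl)))
    c_ang <- acos(cosc)
    k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
    list(x = R * k * cos(p) * sin(dl),
         y = R * k * (cp0 * sin(p) - sp0 * cos(p) * cos(dl)))
  }
  inv <- function(x, y) {
    rho <- sqrt(x^2 + y^2)
    c_ang <- rho / R
    lat <- ifelse(rho < 1e-9, lat0,
                  asin(cos(c_ang) * sp0 + y * sin(c_ang) * cp0 / pmax(rho, 1e-12)) / rad)
    lon <- ifelse(rho < 1e-9, lon0,
                  lon0 + atan2(x * sin(c_ang),
                               rho * cp0 * cos(c_ang) - y * sp0 * sin(c_ang)) / rad)
    list(lon = lon, lat = lat)
  }
  list(fwd = fwd, inv = inv, R = R, lon0 = lon0, lat0 = lat0)
}

# A projection context for working in metres around a geographic centre.
# For a local CRS this is the identity (coordinates are already metres);
# lon/lat for point output are recovered through the CRS anchor.
local_frame <- function(crs, centre_lonlat = NULL) {
  if (is_geographic(crs)) {
    stopifnot(!is.null(centre_lonlat))
    pr <- aeqd_projection(centre_lonlat[1], centre_lonlat[2])
    list(
      to_m   = function(x, y) { p <- pr$fwd(x, y); cbind(p$x, p$y) },
      from_m = function(x, y) { p <- pr$inv(x, y); cbind(p$lon, p$lat) },
      identity = FALSE
    )
  } else {
    list(to_m = function(x, y) cbind(x, y),
         from_m = function(x, y) cbind(x, y),
         identity = TRUE)
  }
}

frame_ring <- function(r, fun) {
  m <- fun(r$x, r$y)
  list(x = m[, 1], y = m[, 2])
}

frame_region <- function(reg, fun) lapply(as_region(reg), frame_ring, fun = fun)

# lon/lat of a point expressed in a CRS
point_to_lonlat <- function(x, y, crs) {
  if (is_geographic(crs)) return(c(x, y))
  pr <- aeqd_projection(crs$lon0, crs$lat0)
  p <- pr$inv(x, y)
  c(p$lon, p$lat)
}

# Planar area of a region in m^2 under a CRS (projects per-region for
# geographic data).
region_area_m2 <- function(reg, crs) {
  reg <- as_region(reg)
  if (!is_geographic(crs)) return(region_area(reg))
  ctr <- region_centroid(reg)
  fr <- local_frame(crs, ctr)
  region_area(frame_region(reg, fr$to_m))
}

# Geodesic area cross-check (m^2); geographic CRS only.
region_area_geodesic <- function(reg, crs) {
  if (!is_geographic(crs)) return(region_area(reg))
  reg <- as_region(reg)
  s <- 0
  for (r in reg) {
    a <- geosphere::areaPolygon(cbind(r$x, r$y))
    s <- s + (if (ring_area_signed(r) >= 0) a else -a)
  }
  abs(s)
}
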