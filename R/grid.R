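EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

earth_surface_km2 <- function() 4 * pi * EARTH_RADIUS_KM^2

#' Mean hexagon area of the aperture-3 icosahedral grid
#'
#' An aperture-3 hexagonal discrete global grid at resolution r tiles the
#' sphere with `10 * 3^r + 2` cells, so the mean cell area is the Earth's
#' surface divided by that count: about 23,320 km² at resolution 7 and
#' 7,770 km² at resolution 8. The planar tessellation used by
#' [assign_hex_cells()] fixes its hexagon area to this value.
#'
#' @param resolution Grid resolution (non-negative integer).
#' @return Mean cell area in km².
#' @export
#' @examples
#' hex_cell_area(7)
hex_cell_area <- function(resolution) {
  if (any(resolution < 0) || any(resolution != floor(resolution))) {
    abort_domain("resolution must be a non-negative integer")
  }
  earth_surface_km2() / (10 * 3^resolution + 2)
}

# Lambert azimuthal equal-area projection on the sphere -------------------
# Equal-area is exact on the sphere, so planar hexagon areas equal true
# surface areas for a regional survey domain.

laea_forward <- function(latitude, longitude, center) {
  phi <- latitude * pi / 180
  lam <- longitude * pi / 180
  phi0 <- center[1] * pi / 180
  lam0 <- center[2] * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  list(x = EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
       y = EARTH_RADIUS_KM * kp *
         (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

laea_inverse <- function(x, y, center) {
  phi0 <- center[1] * pi / 180
  lam0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  phi <- ifelse(rho == 0, phi0,
                asin(cos(c_ang) * sin(phi0) +
                       y * sin(c_ang) * cos(phi0) / rho))
  lam <- ifelse(rho == 0, lam0,
                lam0 + atan2(x * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) -
                               y * sin(phi0) * sin(c_ang)))
  list(latitude = phi * 180 / pi, longitude = lam * 180 / pi)
}

# pointy-top hexagon circumradius for a given cell area
hex_size_km <- function(area_km2) sqrt(2 * area_km2 / (3 * sqrt(3)))

# axial coordinates via cube rounding (pointy-top orientation)
hex_axial_round <- function(qf, rf) {
  x <- qf; z <- rf; y <- -qf - rf
  rx <- round(x); ry <- round(y); rz <- round(z)
  dx <- abs(rx - x); dy <- abs(ry - y); dz <- abs(rz - z)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

#' Assign hauls to equal-area hexagonal grid cells
#'
#' Projects coordinates to a Lambert azimuthal equal-area plane centred on
#' the survey-unit centroid (so planar areas equal surface areas) and bins
#' them into a regular pointy-top hexagonal tessellation whose per-cell area
#' is the aperture-3 icosahedral mean [hex_cell_area()] for the requested
#' resolution. Assignment is deterministic given the centre. The default
#' planar backend can be swapped for a true spherical discrete global grid by
#' passing a different assignment function to [flag_hauls_hex()].
#'
#' @param latitude,longitude Decimal-degree coordinates (WGS84).
#' @param resolution Grid resolution; 7 and 8 are the standard footprint
#'   settings (other non-negative integers are accepted).
#' @param center Optional `c(latitude, longitude)` projection centre; default
#'   is the coordinate centroid.
#' @return Character cell identifiers `"r<resolution>:<q>:<r>"` (axial
#'   hexagon coordinates), one per haul, with the centre stored in attribute
#'   `center`.
#' @export
assign_hex_cells <- function(latitude, longitude, resolution, center = NULL) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort_domain("latitude out of bounds [-90, 90]")
  }
  if (any(abs(longitude) > 180, na.rm = TRUE)) {
    abort_domain("longitude out of bounds [-180, 180]")
  }
  if (is.null(center)) center <- c(mean(latitude), mean(longitude))
  s <- hex_size_km(hex_cell_area(resolution))
  xy <- laea_forward(latitude, longitude, center)
  qf <- (sqrt(3) / 3 * xy$x - 1 / 3 * xy$y) / s
  rf <- (2 / 3 * xy$y) / s
  ax <- hex_axial_round(qf, rf)
  out <- sprintf("r%d:%d:%d", resolution, ax$q, ax$r)
  attr(out, "center") <- center
  out
}

#' Geographic centroid of hexagonal grid cells
#'
#' Inverse of [assign_hex_cells()] for cell centres; used to verify that a
#' haul placed at a cell centroid is assigned back to that cell.
#'
#' @param cells Character cell identifiers as returned by
#'   [assign_hex_cells()].
#' @param center Projection centre `c(latitude, longitude)` used at
#'   assignment time.
#' @return Tibble with `latitude` and `longitude` of each cell centre.
#' @export
hex_cell_centroid <- function(cells, center) {
  parts <- strsplit(cells, ":", fixed = TRUE)
  res <- as.integer(sub("^r", "", vapply(parts, `[[`, "", 1)))
  q <- as.numeric(vapply(parts, `[[`, "", 2))
  r <- as.numeric(vapply(parts, `[[`, "", 3))
  s <- hex_size_km(hex_cell_area(res))
  x <- s * sqrt(3) * (q + r / 2)
  y <- s * 3 / 2 * r
  ll <- laea_inverse(x, y, center)
  tibble(latitude = ll$latitude, longitude = ll$longitude)
}

#' Assign hauls to a BioTIME-style rectangular grid
#'
#' A 5x5 rectangular grid over the latitude/longitude extent of the survey:
#' the cell size is one fifth of the latitudinal and longitudinal range.
#' Bins are half-open `[edge, next_edge)` with the maximum edge closed
#' (indices clamped to 4). A degenerate extent collapses to a single cell.
#'
#' @param latitude,longitude Decimal-degree coordinates.
#' @param extent Optional list with `lat = c(min, max)` and
#'   `lon = c(min, max)`; default is the data range.
#' @param n_bins Bins per axis (default 5).
#' @return Character cell identifiers `"bt:<lat_bin>:<lon_bin>"` with
#'   zero-based bin indices.
#' @export
assign_biotime_cells <- function(latitude, longitude, extent = NULL,
                                 n_bins = 5) {
  if (length(latitude) == 0) abort_domain("no hauls to grid")
  if (is.null(extent)) {
    extent <- list(lat = range(latitude), lon = range(longitude))
  }
  bin <- function(x, rng) {
    span <- diff(rng)
    if (span == 0) return(rep(0L, length(x)))
    pmin(as.integer(floor((x - rng[1]) / (span / n_bins))), n_bins - 1L)
  }
  sprintf("bt:%d:%d", bin(latitude, extent$lat), bin(longitude, extent$lon))
}
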