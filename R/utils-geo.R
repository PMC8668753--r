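# Local projection helpers.
#
# All circle geometry (minimum enclosing circles, foraging buffers, cell-in-
# circle tests) is done in kilometres on an azimuthal equidistant projection
# centred on the data: distances from the centre are exact and local
# distortion is small over a few hundred km, which is all the pipeline needs.

.earth_radius_km <- 6371.0088

#' Project longitude/latitude to local kilometre coordinates
#'
#' Spherical azimuthal equidistant projection centred at `center`. Used for
#' minimum-enclosing-circle geometry and buffer integration, where distances
#' in km matter and the study region spans only a few degrees.
#'
#' @param lon,lat Numeric vectors of coordinates in decimal degrees (WGS84).
#' @param center Length-2 numeric vector `c(lon, lat)` of the projection
#'   centre. Defaults to the centroid of the input points.
#' @return A tibble with columns `x` and `y` in kilometres.
#' @export
#' @examples
#' proj_aeqd(c(4, 4.5), c(54, 54.2), center = c(4, 54))
proj_aeqd <- function(lon, lat, center = c(mean(lon), mean(lat))) {
  stopifnot(length(lon) == length(lat), length(center) == 2)
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  tibble(
    x = .earth_radius_km * k * cos(phi) * sin(lam - lam0),
    y = .earth_radius_km * k *
      (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  )
}

#' Inverse of [proj_aeqd()]
#'
#' @param x,y Numeric vectors of projected coordinates in kilometres.
#' @param center Length-2 numeric vector `c(lon, lat)` used when projecting.
#' @return A tibble with columns `lon` and `lat` in decimal degrees.
#' @export
unproj_aeqd <- function(x, y, center) {
  stopifnot(length(x) == length(y), length(center) == 2)
  lam0 <- center[1] * pi / 180; phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .earth_radius_km
  safe_rho <- ifelse(rho < 1e-12, 1, rho)
  phi <- ifelse(
    rho < 1e-12, phi0,
    asin(cos(c_ang) * sin(phi0) + (y / safe_rho) * sin(c_ang) * cos(phi0))
  )
  lam <- lam0 + atan2(
    x * sin(c_ang),
    safe_rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang)
  )
  lam <- ifelse(rho < 1e-12, lam0, lam)
  tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Assign survey season from a date
#'
#' Strandings are matched to the two bottom-trawl survey quarters: months
#' November to April map to quarter 1 (winter survey) and May to October to
#' quarter 3 (summer survey).
#'
#' @param date A `Date` vector (or something coercible by [as.Date()]).
#' @return A character vector of `"Q1"` / `"Q3"`.
#' @export
#' @examples
#' assign_season(as.Date(c("2012-01-15", "2012-07-01", "2012-11-30")))
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 11 | m <= 4, "Q1", "Q3")
}

# Calendar quarter ("Q1".."Q4") used as the season covariate of the
# foraging-range model (telemetry windows and stranding dates).
calendar_quarter <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  paste0("Q", (m - 1) %/% 3 + 1)
}
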