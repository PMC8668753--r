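#' Build a gridded study region with a coastline mask
#'
#' Defines the raster on which prey fields are predicted and synthetic data
#' are generated: square cells in a local km projection, a land/sea mask
#' given by a coastline running roughly north-south on the eastern side
#' (emulating a shelf sea bounded by a mainland coast), and a smooth depth
#' surface that deepens away from the coast.
#'
#' @param cell_km Cell side length in km (default 5, a typical prediction
#'   grid resolution for shelf-sea survey smoothing).
#' @param xlim,ylim Extent of the grid in projected km.
#' @param center Projection centre `c(lon, lat)` tying the km grid to
#'   geographic coordinates.
#' @param coast A function `f(y)` returning, for each northing `y`, the
#'   easting of the coastline; cells with `x > f(y)` are land.
#' @return An object of class `msfr_grid`: a tibble with one row per cell
#'   (`cell_id`, `x`, `y`, `lon`, `lat`, `depth_m`, `is_sea`) carrying the
#'   grid spec as attributes.
#' @export
#' @examples
#' g <- study_grid(cell_km = 25)
#' table(g$is_sea)
study_grid <- function(cell_km = 5,
                       xlim = c(-150, 150), ylim = c(-150, 150),
                       center = c(lon = 4.0, lat = 54.0),
                       coast = function(y) 100 + 25 * sin(y / 70)) {
  stopifnot(cell_km > 0, diff(xlim) > 0, diff(ylim) > 0)
  xs <- seq(xlim[1] + cell_km / 2, xlim[2] - cell_km / 2, by = cell_km)
  ys <- seq(ylim[1] + cell_km / 2, ylim[2] - cell_km / 2, by = cell_km)
  g <- crossing(y = ys, x = xs)
  ll <- unproj_aeqd(g$x, g$y, center)
  coast_x <- coast(g$y)
  g <- tibble(
    cell_id = seq_len(nrow(g)),
    x = g$x, y = g$y, lon = ll$lon, lat = ll$lat,
    depth_m = pmax(5, 8 + 0.35 * (coast_x - g$x)),
    is_sea = g$x <= coast_x
  )
  if (!any(g$is_sea)) abort("study grid has an empty sea mask")
  structure(g, class = c("msfr_grid", class(g)),
            cell_km = cell_km, center = center, coast = coast,
            xlim = xlim, ylim = ylim)
}

# Easting of the coast at northing y (used to place strandings on the shore).
coast_easting <- function(grid, y) attr(grid, "coast")(y)

# Sea cells of `grid` whose centres fall within `radius_km` of (x0, y0).
cells_in_circle <- function(grid, x0, y0, radius_km) {
  d2 <- (grid$x - x0)^2 + (grid$y - y0)^2
  grid[grid$is_sea & d2 <= radius_km^2, , drop = FALSE]
}
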