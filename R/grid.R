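#' Grid specification for 0.5-degree rasters
#'
#' Defines a regular latitude/longitude grid anchored at the north-west
#' corner (-180 degrees longitude, +90 degrees latitude), row-major from
#' north to south. Cell `(r, c)` (0-based) covers
#' `lat in [90 - res*(r+1), 90 - res*r)` and
#' `lon in [-180 + res*c, -180 + res*(c+1))`; points exactly on the +90
#' latitude or +180 longitude edge clamp into the last valid cell. The
#' global grid at 0.5 degrees is 360 rows by 720 columns; smaller extents
#' cover the north-west sub-window of the globe.
#'
#' @param rows,cols Grid dimensions (global default 360 x 720).
#' @param res Cell size in decimal degrees (default 0.5).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(360, 720)
#' lonlat_to_cell(-180, 90, g)  # cell (0, 0)
#' @export
grid_spec <- function(rows = 360L, cols = 720L, res = 0.5) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L, res > 0)
  structure(
    list(rows = rows, cols = cols, res = res,
         lon_min = -180, lat_max = 90),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g deg, origin (%g, %g)\n",
              x$rows, x$cols, x$res, x$lon_min, x$lat_max))
  invisible(x)
}

#' Map longitude/latitude to grid cell indices
#'
#' Vectorised. Returns 0-based `(row, col)` indices under the half-open
#' cell convention of [grid_spec()]; coordinates outside the grid extent
#' give `NA` (except the +90/+180 edges, which clamp).
#'
#' @param lon,lat Coordinates in decimal degrees (WGS84).
#' @param grid A [grid_spec()].
#' @return A data.frame with integer columns `row` and `col` (0-based).
#' @export
lonlat_to_cell <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- floor((grid$lat_max - lat) / grid$res)
  col <- floor((lon - grid$lon_min) / grid$res)
  # closed outer edges clamp into the last valid cell
  lat_min_edge <- grid$lat_max - grid$rows * grid$res
  lon_max_edge <- grid$lon_min + grid$cols * grid$res
  row[!is.na(lat) & lat == lat_min_edge] <- grid$rows - 1
  col[!is.na(lon) & lon == lon_max_edge] <- grid$cols - 1
  bad <- is.na(row) | is.na(col) | row < 0 | row >= grid$rows |
    col < 0 | col >= grid$cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Bounding box of a grid cell
#'
#' @param row,col 0-based cell indices.
#' @param grid A [grid_spec()].
#' @return A data.frame with `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
cell_bounds <- function(row, col, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(
    lon_min = grid$lon_min + grid$res * col,
    lon_max = grid$lon_min + grid$res * (col + 1),
    lat_min = grid$lat_max - grid$res * (row + 1),
    lat_max = grid$lat_max - grid$res * row
  )
}
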