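#' Define a longitude/latitude grid
#'
#' A grid is described by its extent in decimal degrees (WGS84) and a square
#' cell size in degrees.  Cells are indexed row-major from the north-west
#' corner and are half-open: a cell owns its western and northern edges
#' (`[west, east)` in longitude, `(south, north]` in latitude), so every
#' point falls in exactly one cell.
#'
#' @param extent numeric vector `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param cell_size cell edge length in degrees, > 0.
#' @return an object of class `grid_spec` with fields `extent`, `cell_size`,
#'   `n_cols`, `n_rows`.
#' @examples
#' g <- grid_spec(c(-10, -5, 10, 5), 1)
#' g$n_cols  # 20
#' @export
grid_spec <- function(extent, cell_size) {
  if (length(extent) != 4L || !is.numeric(extent))
    stop("'extent' must be c(lon_min, lat_min, lon_max, lat_max)")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent has non-positive width or height")
  g <- list(
    extent = as.numeric(extent),
    cell_size = as.numeric(cell_size),
    n_cols = as.integer(ceiling((extent[3] - extent[1]) / cell_size - 1e-9)),
    n_rows = as.integer(ceiling((extent[4] - extent[2]) / cell_size - 1e-9))
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, cell %g deg, extent [%g, %g] x [%g, %g]\n",
              x$n_cols, x$n_rows, x$cell_size,
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Map points to grid cell indices
#'
#' Cells are half-open `[west, east) x (south, north]`; points outside the
#' extent (including points exactly on the eastern or southern extent edge)
#' get `NA`.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors in decimal degrees.
#' @return integer vector of row-major cell indices (1-based, from the
#'   north-west corner), `NA` for points outside the grid.
#' @export
cell_index <- function(grid, lon, lat) {
  cs <- grid$cell_size
  col <- floor((lon - grid$extent[1]) / cs) + 1
  # northern edge inclusive: a point on the boundary between two rows
  # belongs to the row to its south
  row <- ceiling((grid$extent[4] - lat) / cs)
  row[lat == grid$extent[4]] <- 1L
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    is.na(lon) | is.na(lat)
  idx <- (row - 1L) * grid$n_cols + col
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Centroids of grid cells
#'
#' @param grid a [grid_spec()].
#' @param idx cell indices; default all cells.
#' @return data.frame with columns `cell`, `lon`, `lat`.
#' @export
cell_centroid <- function(grid, idx = seq_len(n_cells(grid))) {
  idx <- as.integer(idx)
  row <- (idx - 1L) %/% grid$n_cols + 1L
  col <- (idx - 1L) %% grid$n_cols + 1L
  data.frame(
    cell = idx,
    lon = grid$extent[1] + (col - 0.5) * grid$cell_size,
    lat = grid$extent[4] - (row - 0.5) * grid$cell_size
  )
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.  Both arguments are
#' recycled; each is either a length-2 vector `c(lon, lat)` or a two-column
#' matrix.
#'
#' @param p1,p2 points as `c(lon, lat)` or two-column matrices (lon, lat).
#' @return numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(0, 1))  # 111.1949
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371.0)
}

#' Per-pixel area of a grid in square kilometres
#'
#' Spherical cell area, constant within a row of the grid.
#'
#' @param grid a [grid_spec()].
#' @return matrix (`n_rows` x `n_cols`) of cell areas in km^2.
#' @export
cell_area_km2 <- function(grid) {
  ctr <- cell_centroid(grid, seq_len(grid$n_rows) * grid$n_cols)  # one per row
  deg_km <- pi * 6371.0 / 180
  row_area <- (grid$cell_size * deg_km)^2 * cos(ctr$lat * pi / 180)
  matrix(rep(row_area, each = grid$n_cols), nrow = grid$n_rows, byrow = TRUE)
}
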