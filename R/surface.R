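#' Raster surface container
#'
#' Thin container pairing a [grid_spec()] (used as pixel geometry) with a
#' matrix of values (rows from north to south, columns from west to east).
#'
#' @param grid a [grid_spec()] describing the pixel geometry.
#' @param values numeric matrix `n_rows x n_cols`, or a single number to
#'   fill.
#' @return object of class `kernel_surface`.
#' @export
kernel_surface_new <- function(grid, values) {
  if (length(values) == 1L)
    values <- matrix(values, grid$n_rows, grid$n_cols)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  out <- list(grid = grid, values = values)
  class(out) <- "kernel_surface"
  out
}

#' @export
print.kernel_surface <- function(x, ...) {
  cat(sprintf("kernel_surface: %d x %d pixels (%g deg), range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

surface_pixels <- function(surface) cell_centroid(surface$grid)

#' Quartic kernel density surface over points
#'
#' Evaluates a quartic (biweight) kernel density over a set of points on a
#' raster.  Each point contributes
#' \eqn{K(d) = 3/(\pi h^2) (1 - (d/h)^2)^2} for great-circle distance
#' \eqn{d < h} and zero beyond, so each point integrates to unit mass over
#' the plane; values are densities per km^2.
#'
#' @param points two-column matrix or data.frame of (lon, lat).
#' @param bandwidth_km kernel radius \eqn{h} in km, > 0.
#' @param raster a [grid_spec()] giving the pixel geometry.
#' @param weights optional per-point masses (default 1).
#' @return a `kernel_surface`.
#' @export
kernel_surface <- function(points, bandwidth_km, raster, weights = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 1L) stop("at least one point is required")
  if (!is.numeric(bandwidth_km) || bandwidth_km <= 0)
    stop("'bandwidth_km' must be positive")
  if (is.null(weights)) weights <- rep(1, nrow(pts))
  pix <- cell_centroid(raster)
  pixmat <- cbind(pix$lon, pix$lat)
  vals <- numeric(nrow(pixmat))
  h2 <- bandwidth_km^2
  norm <- 3 / (pi * h2)
  for (i in seq_len(nrow(pts))) {
    d <- haversine_km(pts[i, ], pixmat)
    w <- 1 - d * d / h2
    w[w < 0] <- 0
    vals <- vals + weights[i] * norm * w * w
  }
  # pixel centroids come in row-major (north-west first) order
  kernel_surface_new(raster, matrix(vals, raster$n_rows, raster$n_cols,
                                    byrow = TRUE))
}

#' Pearson correlation between two surfaces
#'
#' Pixel-to-pixel Pearson correlation of two surfaces on the same geometry.
#' Pixels that are `NA` in either surface are excluded pairwise.
#'
#' @param s1,s2 `kernel_surface` objects on identical geometry.
#' @return Pearson r.
#' @export
surface_correlation <- function(s1, s2) {
  check_same_geometry(s1, s2)
  x <- as.vector(s1$values); y <- as.vector(s2$values)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 shared pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant surface: correlation undefined")
  stats::cor(x, y)
}

check_same_geometry <- function(s1, s2) {
  g1 <- s1$grid; g2 <- s2$grid
  if (!isTRUE(all.equal(g1$extent, g2$extent)) ||
      !isTRUE(all.equal(g1$cell_size, g2$cell_size)))
    stop("surfaces are not on the same raster geometry")
  invisible(TRUE)
}

#' Label 8-connected components of a pixel mask
#'
#' Breadth-first labelling of TRUE pixels, with diagonal (king-move)
#' adjacency.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      rr <- r + nb_dr; ccn <- cc + nb_dc
      okn <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
      nbr <- (ccn[okn] - 1L) * nr + rr[okn]
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      if (length(nbr)) {
        lab[nbr] <- current
        queue <- c(queue, nbr)
      }
    }
  }
  lab
}

#' Write a surface as an ESRI ASCII grid
#'
#' Plain-text raster export readable by standard GIS software.
#'
#' @param surface a `kernel_surface`.
#' @param path output file path.
#' @param na_value value used for `NA` pixels.
#' @export
write_ascii_grid <- function(surface, path, na_value = -9999) {
  g <- surface$grid
  v <- surface$values
  v[is.na(v)] <- na_value
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$extent[1]),
    sprintf("yllcorner %.10g", g$extent[2]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", na_value)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid into a surface
#'
#' @param path file written by [write_ascii_grid()] or compatible.
#' @return a `kernel_surface`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  ext <- c(val[["xllcorner"]], val[["yllcorner"]],
           val[["xllcorner"]] + val[["ncols"]] * val[["cellsize"]],
           val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]])
  kernel_surface_new(grid_spec(ext, val[["cellsize"]]), v)
}
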