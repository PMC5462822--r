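#' Range-size categories for the endemism interpolation
#'
#' Eleven categories of range size, measured as the great-circle distance
#' (km) from a taxon's range centroid to its farthest record: up to 100 km,
#' 101-200, 201-400, 401-600, 601-800, 801-1000, 1001-1200, 1201-1400,
#' 1401-1600, 1601-2000 and 2001-2150.  Category bounds are treated as
#' half-open intervals `(lower, upper]`, with category 1 covering
#' `[0, 100]`.
#'
#' @return data.frame with `index`, `lower_km`, `upper_km`.
#' @export
range_categories <- function() {
  upper <- c(100, 200, 400, 600, 800, 1000, 1200, 1400, 1600, 2000, 2150)
  data.frame(index = seq_along(upper),
             lower_km = c(0, upper[-length(upper)]),
             upper_km = upper)
}

#' Assign taxa to range-size categories
#'
#' @param max_dist_km numeric vector of centroid-to-farthest-record
#'   distances in km.  Distances above 2150 km are clamped into category 11
#'   with a warning.
#' @return integer vector of category indices (1-11).
#' @export
assign_category <- function(max_dist_km) {
  if (any(max_dist_km < 0)) stop("negative range size")
  cats <- range_categories()
  idx <- findInterval(max_dist_km, cats$upper_km, left.open = TRUE) + 1L
  over <- idx > nrow(cats)
  if (any(over)) {
    warning(sum(over), " taxa with range > 2150 km clamped to category 11")
    idx[over] <- nrow(cats)
  }
  as.integer(idx)
}

#' Geographical Interpolation of Endemism consensus surface
#'
#' Splits taxa into range-size categories, interpolates each category's
#' range centroids with a quartic kernel whose bandwidth equals the
#' category's upper bound in km, rescales each category surface to
#' `[0, 1]` by its own maximum, and assembles the consensus as the sum
#' (optionally the pixelwise maximum) of the rescaled surfaces.
#'
#' @param summaries data.frame from [taxon_range_summary()].
#' @param raster a [grid_spec()] giving the pixel geometry.
#' @param assembly `"sum"` (default) or `"max"`.
#' @param bandwidths optional numeric vector of per-category bandwidths in
#'   km, replacing the default (category upper bound).
#' @return list of class `gie_result`: `consensus` (`kernel_surface`),
#'   `category_surfaces` (named list of standardized surfaces),
#'   `categories` (per-taxon category assignment), `summaries` (the input
#'   table), `metadata`.
#' @export
gie_consensus <- function(summaries, raster, assembly = c("sum", "max"),
                          bandwidths = NULL) {
  assembly <- match.arg(assembly)
  if (NROW(summaries) == 0L) stop("no taxa")
  cats <- range_categories()
  if (is.null(bandwidths)) bandwidths <- cats$upper_km
  cat_idx <- assign_category(summaries$max_dist_km)
  layers <- list()
  for (ci in sort(unique(cat_idx))) {
    sub <- summaries[cat_idx == ci, , drop = FALSE]
    s <- kernel_surface(cbind(sub$centroid_lon, sub$centroid_lat),
                        bandwidth_km = bandwidths[ci], raster = raster)
    mx <- max(s$values)
    if (mx > 0) s$values <- s$values / mx
    layers[[as.character(ci)]] <- s
  }
  vals <- lapply(layers, function(s) s$values)
  consensus_values <- if (assembly == "sum") Reduce(`+`, vals)
                      else Reduce(pmax, vals)
  out <- list(
    consensus = kernel_surface_new(raster, consensus_values),
    category_surfaces = layers,
    categories = data.frame(taxon_id = summaries$taxon_id,
                            category = cat_idx,
                            stringsAsFactors = FALSE),
    summaries = summaries,
    metadata = list(kernel = "quartic", assembly = assembly,
                    bandwidth_km = stats::setNames(bandwidths, cats$index),
                    pixel_deg = raster$cell_size)
  )
  class(out) <- "gie_result"
  out
}

#' @export
print.gie_result <- function(x, ...) {
  cat(sprintf("GIE consensus over %d categories (%d taxa), assembly = %s\n",
              length(x$category_surfaces), nrow(x$categories),
              x$metadata$assembly))
  invisible(x)
}

#' Concentration test of category layers
#'
#' Decides which range-size category layers carry a genuine endemism
#' signal, with two complementary gates evaluated on a coarse calibration
#' grid:
#' \describe{
#'   \item{patchiness}{the layer's max/mean contrast must reach
#'     `contrast_min`.  When the bandwidth approaches the study-window
#'     scale the layer saturates into a smooth background whose peak
#'     height is meaningless after 0-1 standardization; such layers are
#'     excluded.}
#'   \item{congruence}{the layer's maximum stacking depth — the kernel
#'     maximum expressed as an equivalent number of overlapping ranges —
#'     must exceed what the same number of centroids placed uniformly at
#'     random over the window (CSR) produces at the same bandwidth, with
#'     permutation level `alpha`.  Range congruence at the bandwidth
#'     scale, beyond chance, is the defining property of synendemy.}
#' }
#'
#' @param gie a `gie_result`.
#' @param n_sims CSR replicates per category (default 99).
#' @param alpha exceedance level for the congruence gate (default 0.05).
#' @param contrast_min patchiness gate (default 3).
#' @param calibration_cell calibration grid cell in degrees (default 1.5);
#'   observed and simulated statistics use the same grid.
#' @param seed seed for the CSR draws (the caller's RNG state is
#'   restored on exit).
#' @return data.frame with `category`, `n_taxa`, `contrast`, `stacking`,
#'   `p_value`, `admitted`.
#' @export
category_concentration_test <- function(gie, n_sims = 99, alpha = 0.05,
                                        contrast_min = 3,
                                        calibration_cell = 1.5, seed = 1) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(seed)
  sm <- gie$summaries
  g0 <- gie$consensus$grid
  cal <- grid_spec(g0$extent, max(calibration_cell, g0$cell_size))
  pix <- cell_centroid(cal)
  pixmat <- cbind(pix$lon, pix$lat)
  ext <- g0$extent
  bw <- gie$metadata$bandwidth_km
  layer_stats <- function(pts, h) {
    v <- numeric(nrow(pixmat))
    h2 <- h * h
    for (i in seq_len(nrow(pts))) {
      w <- 1 - haversine_km(pts[i, ], pixmat)^2 / h2
      w[w < 0] <- 0
      v <- v + w * w
    }
    m <- mean(v)
    # stacking: kernel max in units of one centroid sitting on a pixel centre
    c(contrast = if (m <= 0) 1 else max(v) / m, stacking = max(v))
  }
  rows <- list()
  for (nm in names(gie$category_surfaces)) {
    ci <- as.integer(nm)
    members <- gie$categories$category == ci
    pts <- cbind(sm$centroid_lon[members], sm$centroid_lat[members])
    h <- bw[[ci]]
    obs <- layer_stats(pts, h)
    n_c <- nrow(pts)
    sims <- vapply(seq_len(n_sims), function(b)
      layer_stats(cbind(stats::runif(n_c, ext[1], ext[3]),
                        stats::runif(n_c, ext[2], ext[4])), h)[["stacking"]],
      numeric(1))
    p <- (1 + sum(sims >= obs[["stacking"]])) / (n_sims + 1)
    rows[[nm]] <- data.frame(category = ci, n_taxa = n_c,
                             contrast = obs[["contrast"]],
                             stacking = obs[["stacking"]], p_value = p,
                             admitted = obs[["contrast"]] >= contrast_min &
                               p <= alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delineate areas of endemism
#'
#' Given a full GIE result, delineation is category-aware.  A category
#' layer is admitted to the delineation only if its centroids are
#' significantly more concentrated than uniform random placement would
#' produce ([category_concentration_test()]); standardization scales every
#' layer to a 0-1 maximum, so without this admission step a near-uniform
#' layer of widespread-species centroids would contribute the same peak
#' height as a sharply stacked layer of narrow endemics while carrying no
#' congruence signal.  The admitted standardized layers are summed and the
#' 8-connected components above `threshold_frac` of the sum's maximum
#' become candidate areas.
#'
#' Supporting (synendemic) taxa are taxa whose range centroid falls inside
#' the area and — when `records` are supplied (recommended) — with at
#' least `support_frac` of their records inside it, the same containment
#' logic the species-to-area fit index uses for "endemic of an area".
#' Candidate areas supported by fewer than `min_synendemics` taxa are
#' dropped, following the definition of an area of endemism as the
#' congruent ranges of two or more restricted taxa.
#'
#' Given a bare `kernel_surface` instead of a `gie_result`, the simple
#' rule is applied: 8-connected components above `threshold_frac` of the
#' global maximum, with no admission or synendemic filtering (supporting
#' taxa, when `summaries` is supplied, are all taxa with centroid inside).
#'
#' @param x a `gie_result` (preferred) or a bare `kernel_surface`.
#' @param threshold_frac fraction of the delineation surface's maximum
#'   (default 0.3).
#' @param summaries optional [taxon_range_summary()] table for the
#'   bare-surface path (the `gie_result` path uses the summaries stored in
#'   the result).
#' @param records occurrence data.frame enabling the record-containment
#'   support rule.
#' @param min_synendemics minimum supporting taxa per area (default 2;
#'   `gie_result` input only).
#' @param support_frac minimum fraction of a supporting taxon's records
#'   inside the area (default 0.9; applied when `records` is given).
#' @param n_sims,alpha,calibration_cell,admission_seed passed to
#'   [category_concentration_test()] (`gie_result` input only).
#' @return list of class `aoe_set`; each element has `id`, `pixels`
#'   (column-major indices into the value matrix), `cells` (raster cell
#'   indices), `polygon` (convex hull of pixel centres), `peak_index`
#'   (maximum of the delineation surface inside), `consensus_peak`,
#'   `supporting_taxa`, `n_synendemics`, `categories` (admitted category
#'   indices; `NULL` for bare-surface input).  Areas are ordered by
#'   decreasing peak index; the admission table is kept as attribute
#'   `admission`.
#' @export
delineate_aoes <- function(x, threshold_frac = 0.3, summaries = NULL,
                           records = NULL, min_synendemics = 2,
                           support_frac = 0.9, n_sims = 99, alpha = 0.05,
                           calibration_cell = 1.5, admission_seed = 1) {
  empty <- structure(list(), class = "aoe_set",
                     threshold = threshold_frac, threshold_value = NA_real_)
  admission <- NULL
  gie_mode <- inherits(x, "gie_result")
  if (gie_mode) {
    admission <- category_concentration_test(x, n_sims = n_sims,
                                             alpha = alpha,
                                             calibration_cell = calibration_cell,
                                             seed = admission_seed)
    use <- as.character(admission$category[admission$admitted])
    if (!length(use)) {
      attr(empty, "admission") <- admission
      return(empty)
    }
    surf_d <- kernel_surface_new(
      x$consensus$grid,
      Reduce(`+`, lapply(x$category_surfaces[use], `[[`, "values")))
    consensus <- x$consensus
    contributing <- as.integer(use)
    summaries <- x$summaries
  } else {
    surf_d <- x
    consensus <- x
    contributing <- NULL
  }
  v <- surf_d$values
  if (!all(is.finite(v))) stop("surface contains non-finite values")
  mx <- max(v)
  if (mx <= 0) {
    attr(empty, "admission") <- admission
    return(empty)
  }
  thr <- threshold_frac * mx
  lab <- label_components(v >= thr)
  ncomp <- max(lab)
  g <- surf_d$grid
  rec_cells <- if (!is.null(records))
    cell_index(g, records$lon, records$lat)
  aoes <- list()
  for (k in seq_len(ncomp)) {
    pix <- which(lab == k)            # column-major matrix indices
    r <- (pix - 1L) %% nrow(v) + 1L
    cc <- (pix - 1L) %/% nrow(v) + 1L
    cells <- (r - 1L) * g$n_cols + cc
    ctr <- cell_centroid(g, cells)
    hull <- grDevices::chull(ctr$lon, ctr$lat)
    supporting <- character(0)
    if (!is.null(summaries)) {
      ci <- cell_index(g, summaries$centroid_lon, summaries$centroid_lat)
      supporting <- summaries$taxon_id[!is.na(ci) & ci %in% cells]
      if (!is.null(records) && length(supporting)) {
        frac_in <- vapply(supporting, function(tx) {
          mean(rec_cells[records$taxon_id == tx] %in% cells)
        }, numeric(1))
        supporting <- supporting[frac_in >= support_frac]
      }
      if (gie_mode && length(supporting) < min_synendemics) next
    }
    aoes[[length(aoes) + 1L]] <- list(
      id = NA_integer_, pixels = pix, cells = cells,
      polygon = cbind(lon = ctr$lon[hull], lat = ctr$lat[hull]),
      peak_index = max(v[pix]),
      consensus_peak = max(consensus$values[pix]),
      supporting_taxa = supporting,
      n_synendemics = length(supporting),
      categories = contributing)
  }
  if (!length(aoes)) {
    attr(empty, "admission") <- admission
    return(empty)
  }
  ord <- order(vapply(aoes, `[[`, numeric(1), "peak_index"), decreasing = TRUE)
  aoes <- aoes[ord]
  for (k in seq_along(aoes)) aoes[[k]]$id <- k
  structure(aoes, class = "aoe_set", threshold = threshold_frac,
            threshold_value = thr, admission = admission)
}

#' @export
print.aoe_set <- function(x, ...) {
  cat(sprintf("%d area(s) of endemism (threshold %.2f of max)\n",
              length(x), attr(x, "threshold")))
  for (a in x)
    cat(sprintf("  #%d: %d pixels, peak %.3f, %d synendemics\n",
                a$id, length(a$pixels), a$peak_index, a$n_synendemics))
  invisible(x)
}

#' Rasterize a polygon onto a grid
#'
#' A cell belongs to the polygon when its centroid falls inside.
#'
#' @param grid a [grid_spec()].
#' @param polygon two-column lon/lat matrix.
#' @return integer vector of cell indices.
#' @export
rasterize_polygon <- function(grid, polygon) {
  ctr <- cell_centroid(grid)
  ctr$cell[point_in_poly(ctr$lon, ctr$lat, as.matrix(polygon))]
}

#' Jaccard overlap between two cell sets
#'
#' @param cells1,cells2 integer vectors of cell indices on the same grid.
#' @return |intersection| / |union|.
#' @export
jaccard_cells <- function(cells1, cells2) {
  length(intersect(cells1, cells2)) / length(union(cells1, cells2))
}
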