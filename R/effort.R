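#' Sampling-effort surface from record density
#'
#' Quartic kernel density of the raw occurrence records (each record has
#' unit mass), used as a spatial index of sampling effort.
#'
#' @param records data.frame with `lon`, `lat`.
#' @param raster a [grid_spec()] pixel geometry.
#' @param bandwidth_km kernel radius in km (default 200).
#' @return a `kernel_surface`.
#' @export
record_density_surface <- function(records, raster, bandwidth_km = 200) {
  if (NROW(records) == 0L) stop("no records")
  kernel_surface(cbind(records$lon, records$lat), bandwidth_km, raster)
}

# Pairwise distance-class structure of a raster geometry, cached because
# the modified t-test is typically applied repeatedly on one geometry.
.endemap_cache <- new.env(parent = emptyenv())

pair_bins <- function(grid, max_pixels = 3000) {
  key <- paste(c(grid$extent, grid$cell_size, max_pixels), collapse = "|")
  hit <- .endemap_cache[[key]]
  if (!is.null(hit)) return(hit)
  ctr <- cell_centroid(grid)
  n_all <- nrow(ctr)
  sel <- seq_len(n_all)
  if (n_all > max_pixels) {
    # regular thinning keeps the lattice structure and stays deterministic
    step <- ceiling(n_all / max_pixels)
    sel <- seq(1L, n_all, by = step)
  }
  ctr <- ctr[sel, ]
  n <- nrow(ctr)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  d <- haversine_km(cbind(ctr$lon[ii], ctr$lat[ii]),
                    cbind(ctr$lon[jj], ctr$lat[jj]))
  width <- grid$cell_size * pi * 6371 / 180  # one pixel in km
  bin <- pmax(1L, as.integer(ceiling(d / width)))
  ord <- order(bin)
  res <- list(sel = sel, i = ii[ord], j = jj[ord], bin = bin[ord],
              n = n, n_k = tabulate(bin))
  .endemap_cache[[key]] <- res
  res
}

#' Correlation between surfaces with corrected degrees of freedom
#'
#' Pearson correlation between two surfaces with a modified t-test for
#' spatially autocorrelated data (Clifford, Richardson & Hemon 1989;
#' Dutilleul 1993).  The effective sample size is estimated from the
#' empirical spatial autocorrelation functions of both surfaces, computed
#' on distance classes one pixel wide, and the t-test uses
#' `n_effective - 2` degrees of freedom.  Adding constants or rescaling
#' either surface leaves the effective sample size unchanged.
#'
#' On large rasters the pairwise distance structure is computed on a
#' regular thinning of at most `max_pixels` pixels.
#'
#' @param s1,s2 `kernel_surface` objects on the same geometry.
#' @param max_pixels cap on the number of pixels entering the pair census.
#' @return list of class `corrected_cor`: `r`, `n_effective`, `t_stat`,
#'   `df`, `p_value`, `naive_p`, `n_pixels`.
#' @export
corrected_correlation <- function(s1, s2, max_pixels = 3000) {
  check_same_geometry(s1, s2)
  pb <- pair_bins(s1$grid, max_pixels)
  x <- as.vector(t(s1$values))[pb$sel]  # row-major to match cell indices
  y <- as.vector(t(s2$values))[pb$sel]
  ok <- !is.na(x) & !is.na(y)
  if (!all(ok)) {
    # recompute pair structure on the complete-case subset
    keep <- which(ok)
    kmap <- match(seq_along(x), keep)
    pi2 <- kmap[pb$i]; pj2 <- kmap[pb$j]
    pok <- !is.na(pi2) & !is.na(pj2)
    pb <- list(i = pi2[pok], j = pj2[pok], bin = pb$bin[pok],
               n = length(keep), n_k = tabulate(pb$bin[pok]))
    x <- x[keep]; y <- y[keep]
  }
  n <- pb$n
  if (n < 5L) stop("too few pixels")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("constant surface")
  r <- stats::cor(x, y)
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy
  px <- zx[pb$i] * zx[pb$j]
  py <- zy[pb$i] * zy[pb$j]
  rho_x <- rowsum(px, pb$bin) / pmax(pb$n_k[sort(unique(pb$bin))], 1)
  rho_y <- rowsum(py, pb$bin) / pmax(pb$n_k[sort(unique(pb$bin))], 1)
  n_k <- pb$n_k[sort(unique(pb$bin))]
  # var(r) under independence: lag-0 terms plus twice the unordered pairs
  var_r <- (n + 2 * sum(n_k * rho_x * rho_y)) / n^2
  var_r <- max(var_r, 1 / n^2)
  n_eff <- min(1 / var_r + 1, n)
  df <- n_eff - 2
  t_naive <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  naive_p <- 2 * stats::pt(-abs(t_naive), n - 2)
  if (df < 1) {
    warning("effective sample size below 3; p-value indeterminate")
    t_stat <- NA_real_; p <- NA_real_
  } else {
    t_stat <- r * sqrt(df / max(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(r = r, n_effective = n_eff, t_stat = t_stat, df = df,
                 p_value = p, naive_p = naive_p, n_pixels = n),
            class = "corrected_cor")
}

#' @export
print.corrected_cor <- function(x, ...) {
  cat(sprintf("r = %.3f, n = %d pixels, effective n = %.1f, t = %.2f, p = %.4g (naive p = %.4g)\n",
              x$r, x$n_pixels, x$n_effective, x$t_stat, x$p_value, x$naive_p))
  invisible(x)
}

#' Smoothed Gaussian noise surface
#'
#' White noise on the raster smoothed with a Gaussian moving-average
#' filter (reflecting edges), rescaled to unit variance.  Used to study
#' the behaviour of correlation tests under spatial autocorrelation.
#'
#' @param raster a [grid_spec()].
#' @param sigma_pixels Gaussian smoothing radius in pixels (0 = white
#'   noise).
#' @param seed integer seed.
#' @return a `kernel_surface`.
#' @export
smoothed_noise_surface <- function(raster, sigma_pixels = 2, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(raster$n_rows * raster$n_cols),
              raster$n_rows, raster$n_cols)
  if (sigma_pixels > 0) {
    half <- max(1L, ceiling(3 * sigma_pixels))
    kern <- stats::dnorm(-half:half, sd = sigma_pixels)
    kern <- kern / sum(kern)
    pad_filter <- function(m) {
      # reflect-pad then convolve rows
      idx <- c(pmin(half:1, nrow(m)), seq_len(nrow(m)),
               nrow(m) - pmin(1:half, nrow(m) - 1) + 1)
      mp <- m[idx, , drop = FALSE]
      out <- apply(mp, 2, function(col) stats::filter(col, kern, sides = 2))
      out[(half + 1):(half + nrow(m)), , drop = FALSE]
    }
    z <- pad_filter(z)
    z <- t(pad_filter(t(z)))
  }
  z <- (z - mean(z)) / stats::sd(z)
  kernel_surface_new(raster, z)
}
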