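#' Cell-to-cell Bray-Curtis dissimilarity matrix
#'
#' On presence/absence data the Bray-Curtis index reduces to the Sorensen
#' dissimilarity `(b + c) / (2a + b + c)` where `a` counts shared taxa and
#' `b`, `c` the taxa unique to each cell.  An abundance mode using raw
#' per-cell record counts is available but off by default because the
#' pipeline is defined on the binary matrix.
#'
#' @param pam a `pam`.
#' @param mode `"binary"` (default) or `"abundance"`.
#' @return a `dissim` object: full symmetric matrix with attributes
#'   `cell_ids` and `flavor`.
#' @export
bray_curtis_matrix <- function(pam, mode = c("binary", "abundance")) {
  mode <- match.arg(mode)
  if (length(pam$cells) < 2L) stop("need at least 2 cells")
  x <- pam$m
  if (mode == "abundance") {
    # per-cell record counts spread over the cell's taxa are not tracked;
    # abundance mode weights presences by the cell's record count
    x <- pam$m * as.numeric(pam$record_counts)
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dissim_new(d, pam$cells, "total")
}

dissim_new <- function(d, cell_ids, flavor) {
  dimnames(d) <- list(paste0("cell_", cell_ids), paste0("cell_", cell_ids))
  structure(d, cell_ids = cell_ids, flavor = flavor, class = c("dissim", "matrix"))
}

#' Partition beta diversity into turnover and nestedness
#'
#' Additive pairwise partition of the total Sorensen dissimilarity into a
#' turnover component (Simpson dissimilarity, `min(b,c) / (a + min(b,c))`)
#' and a nestedness-resultant component (total minus turnover), following
#' the Baselga framework.  The identity `total = turnover + nestedness`
#' holds elementwise.
#'
#' @param pam a `pam` (binary matrix).
#' @return list with `turnover`, `nestedness`, `total` (`dissim` objects).
#' @export
partition_beta <- function(pam) {
  x <- pam$m
  if (nrow(x) < 2L) stop("need at least 2 cells")
  A <- tcrossprod(x)              # shared presences
  ri <- rowSums(x)
  B <- outer(ri, rep(1, length(ri))) - A  # unique to row cell
  C <- t(B)
  tot <- (B + C) / (2 * A + B + C)
  mn <- pmin(B, C)
  turn <- mn / (A + mn)
  turn[A + mn == 0] <- 0          # cells are non-empty, defensive only
  diag(tot) <- 0; diag(turn) <- 0
  nest <- tot - turn
  list(turnover = dissim_new(turn, pam$cells, "turnover"),
       nestedness = dissim_new(nest, pam$cells, "nestedness"),
       total = dissim_new(tot, pam$cells, "total"))
}

#' Non-metric multidimensional scaling with random starts
#'
#' Kruskal non-metric MDS (global model, stress-1) of a dissimilarity
#' matrix, run from `n_starts` random configurations plus one metric
#' (principal-coordinates) start, keeping the solution with the lowest
#' stress.  Axis scores are centred.  The non-metric fit is
#' `R^2 = 1 - stress^2`; the linear fit is the squared correlation between
#' the monotone-fitted distances and the ordination distances.
#'
#' @param d a `dissim` or `dist`-coercible matrix.
#' @param k number of axes (default 3).
#' @param n_starts number of random starts (default 100).
#' @param seed integer seed making the run reproducible.
#' @return list of class `nmds_result`: `scores` (n x k, centred),
#'   `stress`, `nonmetric_R2`, `linear_R2`, `n_starts`, `best_start`.
#' @export
nmds <- function(d, k = 3, n_starts = 100, seed = 1) {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (n < k + 2) stop("need at least k + 2 objects")
  set.seed(seed)
  best <- NULL; best_start <- NA_integer_
  init0 <- tryCatch(stats::cmdscale(dd, k = k), error = function(e) NULL)
  for (s in 0:n_starts) {
    init <- if (s == 0L) init0 else matrix(stats::rnorm(n * k), n, k)
    if (is.null(init)) next
    fit <- tryCatch(
      vegan::monoMDS(dd, y = init, k = k, model = "global",
                     maxit = 500, smin = 1e-5, sfgrmin = 1e-8),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit; best_start <- s
    }
  }
  if (is.null(best)) stop("NMDS failed to converge in all starts")
  scores <- scale(best$points, center = TRUE, scale = FALSE)
  colnames(scores) <- paste0("NMDS", seq_len(k))
  rownames(scores) <- labels(dd)
  lin <- stats::cor(best$dist, best$dhat)^2
  structure(list(scores = scores, stress = best$stress,
                 nonmetric_R2 = 1 - best$stress^2, linear_R2 = lin,
                 n_starts = n_starts, best_start = best_start),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, %d axes, stress %.4f (non-metric R2 %.3f, linear R2 %.3f)\n",
              nrow(x$scores), ncol(x$scores), x$stress, x$nonmetric_R2,
              x$linear_R2))
  invisible(x)
}

#' Adjacency weights between occupied grid cells
#'
#' Binary queen (default) or rook adjacency between the occupied cells of a
#' presence/absence matrix, optionally row-standardized.
#'
#' @param pam a `pam`.
#' @param scheme `"queen"` or `"rook"`.
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return square weight matrix over `pam$cells`.
#' @export
cell_adjacency <- function(pam, scheme = c("queen", "rook"),
                           row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  g <- pam$grid
  r <- (pam$cells - 1L) %/% g$n_cols
  cc <- (pam$cells - 1L) %% g$n_cols
  dr <- abs(outer(r, r, "-"))
  dc <- abs(outer(cc, cc, "-"))
  W <- if (scheme == "queen") (dr <= 1 & dc <= 1) else (dr + dc == 1)
  W <- W * 1
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  dimnames(W) <- list(paste0("cell_", pam$cells), paste0("cell_", pam$cells))
  W
}

#' Moran's I with a permutation test
#'
#' Moran's I of values observed at spatial units with a given weight
#' matrix, with a two-sided permutation p-value obtained by randomly
#' relabelling the values.
#'
#' @param values numeric vector.
#' @param weights square weight matrix (e.g. [cell_adjacency()]).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `moran_result`: `I`, `expected_I`, `p_value`,
#'   `n_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = 1) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 units")
  if (stats::sd(values) == 0) stop("zero variance")
  W <- as.matrix(weights)
  stopifnot(nrow(W) == n, ncol(W) == n)
  S0 <- sum(W)
  moran_stat <- function(z) (n / S0) * sum(z * (W %*% z)) / sum(z * z)
  z <- values - mean(values)
  I_obs <- moran_stat(z)
  E_I <- -1 / (n - 1)
  set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(i) sample(z), numeric(n))
  I_perm <- (n / S0) * colSums(Z * (W %*% Z)) / colSums(Z * Z)
  p <- (1 + sum(abs(I_perm - E_I) >= abs(I_obs - E_I) - 1e-12)) / (n_perm + 1)
  structure(list(I = I_obs, expected_I = E_I, p_value = p, n_perm = n_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), permutation p = %.4g (%d permutations)\n",
              x$I, x$expected_I, x$p_value, x$n_perm))
  invisible(x)
}

#' Ordinary kriging of point values onto a raster
#'
#' Ordinary kriging with an exponential variogram fitted by weighted least
#' squares (Cressie weights, bin count over squared model value) to the
#' empirical semivariogram on equal-width distance bins.  The predictor is
#' exact at the data points.  If the variogram fit fails, a linear
#' variogram fitted by weighted regression is used, with a warning.
#'
#' @param points two-column matrix or data.frame of (lon, lat).
#' @param values numeric vector of observations (e.g. NMDS axis scores).
#' @param raster a [grid_spec()] pixel geometry.
#' @param n_bins number of semivariogram distance bins (default 15).
#' @param params optional list with `nugget`, `sill`, `range_km` fixing the
#'   exponential variogram instead of fitting it.
#' @return list of class `krige_result`: `prediction` and `variance`
#'   (`kernel_surface`s), `variogram` (list: model, nugget, sill/slope,
#'   range, empirical table), and `predict` (a function mapping a
#'   two-column lon/lat matrix to kriging predictions, exact at the data
#'   points).
#' @export
krige_axis <- function(points, values, raster, n_bins = 15, params = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 10L) stop("need at least 10 points")
  if (length(values) != n) stop("length mismatch")
  pix <- cell_centroid(raster)
  if (stats::sd(values) < 1e-12) {
    # constant field: kriging returns the constant with zero variance
    return(structure(list(
      prediction = kernel_surface_new(raster, values[1]),
      variance = kernel_surface_new(raster, 0),
      variogram = list(model = "constant"),
      predict = function(newpoints) rep(values[1], NROW(newpoints))),
      class = "krige_result"))
  }
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  dp <- haversine_km(cbind(pts[ii, 1], pts[ii, 2]),
                     cbind(pts[jj, 1], pts[jj, 2]))
  sv <- 0.5 * (values[ii] - values[jj])^2
  maxd <- max(dp)
  bin <- pmin(n_bins, pmax(1L, ceiling(dp / (maxd / n_bins))))
  emp <- data.frame(
    dist = as.numeric(tapply(dp, bin, mean)),
    gamma = as.numeric(tapply(sv, bin, mean)),
    n = as.numeric(tabulate(bin, n_bins))[sort(unique(bin))]
  )
  vario <- if (!is.null(params)) {
    list(model = "exponential", nugget = params$nugget, sill = params$sill,
         range_km = params$range_km, empirical = emp,
         gamma_fun = function(d) ifelse(d <= 0, 0,
           params$nugget + params$sill * (1 - exp(-d / params$range_km))))
  } else fit_exponential_variogram(emp)
  gamma_fun <- vario$gamma_fun
  # kriging system in semivariogram form; gamma(0) = 0 keeps it exact
  G <- matrix(0, n, n)
  G[cbind(ii, jj)] <- gamma_fun(dp)
  G <- G + t(G)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  d0 <- haversine_km_cross(pts, cbind(pix$lon, pix$lat))
  B <- rbind(gamma_fun(d0), 1)
  L <- Ainv %*% B
  pred <- as.vector(crossprod(L[seq_len(n), , drop = FALSE], values))
  pvar <- pmax(colSums(B * L), 0)
  predict_fun <- function(newpoints) {
    np <- as.matrix(newpoints)[, 1:2, drop = FALSE]
    dn <- haversine_km_cross(pts, np)
    Bn <- rbind(gamma_fun(dn), 1)
    Ln <- Ainv %*% Bn
    as.vector(crossprod(Ln[seq_len(n), , drop = FALSE], values))
  }
  structure(list(
    prediction = kernel_surface_new(raster, matrix(pred, raster$n_rows,
                                                   raster$n_cols, byrow = TRUE)),
    variance = kernel_surface_new(raster, matrix(pvar, raster$n_rows,
                                                 raster$n_cols, byrow = TRUE)),
    variogram = vario[c("model", "nugget", "sill", "range_km", "empirical")],
    predict = predict_fun),
    class = "krige_result")
}

# n1 x n2 great-circle distance matrix, looping over the smaller side
haversine_km_cross <- function(p1, p2) {
  out <- matrix(0, nrow(p1), nrow(p2))
  for (i in seq_len(nrow(p1)))
    out[i, ] <- haversine_km(p1[i, ], p2)
  out
}

fit_exponential_variogram <- function(emp) {
  emp <- emp[is.finite(emp$gamma) & emp$n > 0, , drop = FALSE]
  maxd <- max(emp$dist)
  gmax <- max(emp$gamma)
  # weighted least squares with empirical weights n_j / gamma_j^2
  w <- emp$n / pmax(emp$gamma, 0.01 * gmax)^2
  obj <- function(p) {
    g <- p[1] + p[2] * (1 - exp(-emp$dist / p[3]))
    sum(w * (emp$gamma - g)^2)
  }
  init <- c(max(min(emp$gamma), 1e-8), max(gmax - min(emp$gamma), 1e-8),
            maxd / 3)
  fit <- tryCatch(stats::optim(init, obj, method = "L-BFGS-B",
                               lower = c(0, 1e-10 * gmax, maxd / 100),
                               upper = c(gmax, 10 * gmax, 10 * maxd),
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value) &&
      fit$par[2] * (1 - exp(-maxd / fit$par[3])) > 1e-6 * gmax) {
    nugget <- fit$par[1]; sill <- fit$par[2]; rng <- fit$par[3]
    return(list(model = "exponential", nugget = nugget, sill = sill,
                range_km = rng, empirical = emp,
                gamma_fun = function(d) ifelse(d <= 0, 0,
                  nugget + sill * (1 - exp(-d / rng)))))
  }
  warning("exponential variogram fit failed; falling back to linear variogram")
  lmfit <- stats::lm(gamma ~ dist, data = emp, weights = emp$n)
  a <- max(stats::coef(lmfit)[1], 0); bslope <- max(stats::coef(lmfit)[2], 1e-12)
  list(model = "linear", nugget = a, sill = NA_real_, range_km = NA_real_,
       empirical = emp,
       gamma_fun = function(d) ifelse(d <= 0, 0, a + bslope * d))
}

#' Combine three surfaces into an RGB composite
#'
#' Min-max rescales each axis surface to `[0, 255]` and assigns axis 1 to
#' red, axis 2 to green and axis 3 to blue.  A constant surface maps to
#' 128 with a warning.
#'
#' @param s1,s2,s3 `kernel_surface`s on the same geometry.
#' @return array `n_rows x n_cols x 3` of class `rgb_raster` with the grid
#'   kept as attribute `grid`.
#' @export
rgb_composite <- function(s1, s2, s3) {
  check_same_geometry(s1, s2); check_same_geometry(s1, s3)
  chan <- function(s) {
    v <- s$values
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("constant band mapped to 128")
      return(matrix(128, nrow(v), ncol(v)))
    }
    (v - rng[1]) / diff(rng) * 255
  }
  out <- array(NA_real_, c(nrow(s1$values), ncol(s1$values), 3))
  out[, , 1] <- chan(s1); out[, , 2] <- chan(s2); out[, , 3] <- chan(s3)
  structure(out, grid = s1$grid, class = "rgb_raster")
}

#' Run the full composition-break pipeline
#'
#' Convenience wrapper chaining the six steps: presence/absence input,
#' Bray-Curtis matrix, NMDS (k axes, random starts), Moran's I premise
#' check on each axis, ordinary kriging of each axis onto the raster, and
#' the RGB composite.
#'
#' @param pam a `pam` (already filtered with [filter_cells_by_records()] as
#'   appropriate).
#' @param raster a [grid_spec()] pixel geometry.
#' @param k axes (default 3).
#' @param n_starts NMDS random starts (default 100).
#' @param n_perm Moran permutations (default 999).
#' @param seed integer seed for NMDS and the permutation tests.
#' @param flavor `"total"`, `"turnover"` or `"nestedness"`.
#' @return list: `dissimilarity`, `ordination`, `moran` (per axis),
#'   `surfaces` (per-axis `krige_result`s), `rgb`.
#' @export
composition_pipeline <- function(pam, raster, k = 3, n_starts = 100,
                                 n_perm = 999, seed = 1,
                                 flavor = c("total", "turnover", "nestedness")) {
  flavor <- match.arg(flavor)
  d <- if (flavor == "total") bray_curtis_matrix(pam)
       else partition_beta(pam)[[flavor]]
  ord <- nmds(d, k = k, n_starts = n_starts, seed = seed)
  W <- cell_adjacency(pam, "queen")
  ctr <- cell_centroid(pam$grid, pam$cells)
  moran <- lapply(seq_len(k), function(ax)
    morans_i(ord$scores[, ax], W, n_perm = n_perm, seed = seed + ax))
  surfaces <- lapply(seq_len(k), function(ax)
    krige_axis(cbind(ctr$lon, ctr$lat), ord$scores[, ax], raster))
  rgb <- if (k >= 3)
    rgb_composite(surfaces[[1]]$prediction, surfaces[[2]]$prediction,
                  surfaces[[3]]$prediction)
  list(dissimilarity = d, ordination = ord, moran = moran,
       surfaces = surfaces, rgb = rgb, flavor = flavor)
}
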