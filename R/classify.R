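#' Stack surfaces into a pixel-by-band matrix
#'
#' @param surfaces list of `kernel_surface`s on the same geometry.
#' @return matrix with one row per pixel (row-major from the north-west)
#'   and one column per surface; attribute `grid` keeps the geometry.
#' @export
surface_stack <- function(surfaces) {
  for (s in surfaces[-1]) check_same_geometry(surfaces[[1]], s)
  x <- vapply(surfaces, function(s) as.vector(t(s$values)),
              numeric(length(surfaces[[1]]$values)))
  colnames(x) <- names(surfaces)
  attr(x, "grid") <- surfaces[[1]]$grid
  x
}

gaussian_logdens <- function(x, mean, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z * z)
}

em_gmm <- function(x, k, seed, max_iter = 300, tol = 1e-8, ridge = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 5, iter.max = 50)
  prop <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  prop[prop == 0] <- 1 / n
  prop <- prop / sum(prop)
  means <- lapply(seq_len(k), function(j) {
    if (sum(km$cluster == j) > 0) colMeans(x[km$cluster == j, , drop = FALSE])
    else x[sample(n, 1), ]
  })
  covs <- lapply(seq_len(k), function(j) {
    xs <- x[km$cluster == j, , drop = FALSE]
    s <- if (nrow(xs) > d) stats::cov(xs) else stats::cov(x)
    s + diag(ridge, d)
  })
  loglik_trace <- numeric(0)
  prev <- -Inf
  regularized <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      s <- covs[[j]]
      dens <- tryCatch(gaussian_logdens(x, means[[j]], s),
                       error = function(e) NULL)
      if (is.null(dens)) {
        regularized <<- TRUE
        dens <- gaussian_logdens(x, means[[j]],
                                 s + diag(1e-4 * mean(diag(s)) + 1e-10, d))
      }
      dens + log(prop[j])
    }, numeric(n))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    if (ll < prev - 1e-6)
      warning("EM log-likelihood decreased (numerical issue)")
    converged <- is.finite(prev) && ll - prev < tol * abs(ll)
    prev <- ll
    if (converged) break
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    prop <- nk / n
    for (j in seq_len(k)) {
      means[[j]] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, means[[j]])
      s <- crossprod(xc * resp[, j], xc) / nk[j]
      ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10 * max(abs(ev))) {
        s <- s + diag(1e-6 * mean(diag(s)) + 1e-12, d)
        regularized <- TRUE
      }
      covs[[j]] <- s
    }
  }
  if (regularized)
    warning("degenerate covariance regularized with a small ridge")
  post <- exp(logd - lse)
  labels <- max.col(post)
  npar <- k - 1 + k * d + k * d * (d + 1) / 2
  list(k = k, labels = labels, means = means, covariances = covs,
       proportions = prop, loglik = prev, loglik_trace = loglik_trace,
       bic = -2 * prev + npar * log(n), n_iter = length(loglik_trace))
}

#' Unsupervised maximum-likelihood classification
#'
#' Gaussian mixture models fitted by expectation-maximization on the
#' per-pixel band vectors of a composition raster (full covariances,
#' k-means initialization), one fit per candidate group count.  The
#' log-likelihood trace is retained so its monotonicity can be checked;
#' BIC is reported per group count (lower is better).
#'
#' @param x a surface list, `rgb_raster`, or numeric matrix (pixels x
#'   bands); `NA` rows are dropped.
#' @param n_groups integer vector of group counts, each in 2..11.
#' @param seed integer seed (k-means initialization).
#' @return list of class `ml_classification`: one result per group count
#'   with `labels`, `means`, `covariances`, `proportions`, `loglik`,
#'   `loglik_trace`, `bic`, and `class_raster` (a `kernel_surface` of
#'   integer labels) when pixel geometry is available.
#' @export
ml_classify <- function(x, n_groups = 2:11, seed = 1) {
  if (any(n_groups < 2 | n_groups > 11))
    stop("group counts must be between 2 and 11")
  grid <- NULL
  if (inherits(x, "rgb_raster")) {
    grid <- attr(x, "grid")
    x <- vapply(1:3, function(b) as.vector(t(x[, , b])),
                numeric(length(x[, , 1])))
  } else if (is.list(x) && inherits(x[[1]], "kernel_surface")) {
    x <- surface_stack(x)
    grid <- attr(x, "grid")
  }
  x <- as.matrix(x)
  ok <- stats::complete.cases(x)
  xc <- x[ok, , drop = FALSE]
  if (nrow(xc) < max(n_groups) * 10)
    stop("too few valid pixels for the requested group counts")
  fits <- lapply(n_groups, function(k) {
    fit <- em_gmm(xc, k, seed = seed + k)
    if (!is.null(grid)) {
      lab <- rep(NA_real_, nrow(x))
      lab[ok] <- fit$labels
      fit$class_raster <- kernel_surface_new(
        grid, matrix(lab, grid$n_rows, grid$n_cols, byrow = TRUE))
    }
    fit
  })
  names(fits) <- paste0("k", n_groups)
  structure(fits, class = "ml_classification")
}

#' @export
print.ml_classification <- function(x, ...) {
  bics <- vapply(x, `[[`, numeric(1), "bic")
  for (nm in names(x))
    cat(sprintf("  %s: loglik %.1f, BIC %.1f%s\n", nm, x[[nm]]$loglik,
                x[[nm]]$bic, if (bics[nm] == min(bics)) "  <- best" else ""))
  invisible(x)
}

#' Discriminant test of candidate region schemes
#'
#' Samples `n_points` pixels uniformly (without replacement) inside each
#' candidate region polygon, fits a linear discriminant model of the axis
#' scores on region labels, and reports resubstitution and leave-one-out
#' hit percentages with the confusion matrix.
#'
#' @param surfaces list of axis-score `kernel_surface`s.
#' @param regions named list of polygons (two-column lon/lat matrices).
#'   Overlapping regions are an error.
#' @param n_points points sampled per region (default 100).
#' @param seed integer seed.
#' @return list of class `discriminant_report`: `confusion`
#'   (resubstitution), `hit_pct` per region, `overall_hit_pct`,
#'   `cv_confusion`, `cv_hit_pct`, `skipped`.
#' @export
discriminant_test <- function(surfaces, regions, n_points = 100, seed = 1) {
  stack <- surface_stack(surfaces)
  grid <- attr(stack, "grid")
  ctr <- cell_centroid(grid)
  if (is.null(names(regions)))
    names(regions) <- paste0("region_", seq_along(regions))
  membership <- matrix(FALSE, nrow(ctr), length(regions))
  for (ri in seq_along(regions))
    membership[, ri] <- point_in_poly(ctr$lon, ctr$lat,
                                      as.matrix(regions[[ri]]))
  if (any(rowSums(membership) > 1)) stop("overlapping regions")
  set.seed(seed)
  xs <- list(); labs <- character(0); skipped <- character(0)
  for (ri in seq_along(regions)) {
    inside <- which(membership[, ri] & stats::complete.cases(stack))
    if (length(inside) < n_points) {
      warning("region '", names(regions)[ri], "' has fewer than ", n_points,
              " samplable pixels; skipped")
      skipped <- c(skipped, names(regions)[ri])
      next
    }
    pick <- sample(inside, n_points)
    xs[[length(xs) + 1L]] <- stack[pick, , drop = FALSE]
    labs <- c(labs, rep(names(regions)[ri], n_points))
  }
  if (length(xs) < 2L) stop("need at least two samplable regions")
  X <- do.call(rbind, xs)
  y <- factor(labs)
  fit <- MASS::lda(X, grouping = y)
  pred <- stats::predict(fit, X)$class
  conf <- table(truth = y, predicted = pred)
  cv <- MASS::lda(X, grouping = y, CV = TRUE)$class
  cv_conf <- table(truth = y, predicted = cv)
  hit <- 100 * diag(conf) / rowSums(conf)
  cv_hit <- 100 * diag(cv_conf) / rowSums(cv_conf)
  structure(list(confusion = conf, hit_pct = hit,
                 overall_hit_pct = 100 * sum(diag(conf)) / length(y),
                 cv_confusion = cv_conf, cv_hit_pct = cv_hit,
                 cv_overall_hit_pct = 100 * sum(diag(cv_conf)) / length(y),
                 skipped = skipped, n_points = n_points),
            class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  cat(sprintf("discriminant analysis: overall hit %.1f%% (leave-one-out %.1f%%)\n",
              x$overall_hit_pct, x$cv_overall_hit_pct))
  print(x$confusion)
  invisible(x)
}
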