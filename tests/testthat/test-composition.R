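test_that("binary Bray-Curtis equals the Sorensen formula on small cases", {
  m <- rbind(c(1, 1, 0), c(1, 1, 0))  # identical cells
  colnames(m) <- c("A", "B", "C")
  expect_equal(unname(bray_curtis_matrix(pam_from_matrix(m))[1, 2]), 0)
  m2 <- rbind(c(1, 0), c(0, 1))       # disjoint cells
  expect_equal(unname(bray_curtis_matrix(pam_from_matrix(m2))[1, 2]), 1)
  m3 <- rbind(c(1, 1, 0), c(0, 1, 1)) # {A,B} vs {B,C}
  expect_equal(unname(bray_curtis_matrix(pam_from_matrix(m3))[1, 2]), 0.5)
})

test_that("beta partition matches hand-derived Baselga components", {
  # nested pair: cell 2's taxa are a subset of cell 1's
  m <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0))
  pb <- partition_beta(pam_from_matrix(m))
  expect_equal(unname(pb$turnover[1, 2]), 0)
  expect_equal(unname(pb$nestedness[1, 2]), unname(pb$total[1, 2]))
  # a = 2 shared, b = 1, c = 3: total 1/2, turnover 1/3, nestedness 1/6
  m2 <- rbind(c(1, 1, 1, 0, 0, 0),
              c(1, 1, 0, 1, 1, 1))
  pb2 <- partition_beta(pam_from_matrix(m2))
  expect_equal(unname(pb2$total[1, 2]), 0.5)
  expect_equal(unname(pb2$turnover[1, 2]), 1 / 3)
  expect_equal(unname(pb2$nestedness[1, 2]), 1 / 6)
})

test_that("NMDS recovers an exactly embeddable configuration", {
  set.seed(2)
  pts <- matrix(runif(40), 20, 2)
  d <- dist(pts)
  ord <- nmds(d, k = 2, n_starts = 20, seed = 1)
  expect_lte(ord$stress, 1e-3)
  expect_equal(ord$nonmetric_R2, 1 - ord$stress^2)
  expect_equal(colMeans(ord$scores), c(NMDS1 = 0, NMDS2 = 0))
})

test_that("NMDS stress is monotone in the number of axes", {
  pam <- random_pam(15, 30, seed = 4)
  d <- bray_curtis_matrix(pam)
  s2 <- nmds(d, k = 2, n_starts = 15, seed = 3)$stress
  s3 <- nmds(d, k = 3, n_starts = 15, seed = 3)$stress
  expect_lte(s3, s2 + 1e-6)
})

test_that("NMDS runs are reproducible under a fixed seed", {
  pam <- random_pam(12, 25, seed = 5)
  d <- bray_curtis_matrix(pam)
  a <- nmds(d, k = 2, n_starts = 10, seed = 9)
  b <- nmds(d, k = 2, n_starts = 10, seed = 9)
  expect_identical(a$scores, b$scores)
  expect_identical(a$stress, b$stress)
})

test_that("Moran's I is -1 on a rook checkerboard and finds gradients", {
  g <- grid_spec(c(0, 0, 6, 6), 1)
  m <- matrix(1L, 36, 1, dimnames = list(paste0("cell_", 1:36), "sp1"))
  pam <- pam_from_matrix(m, g)
  pam$cells <- 1:36
  W <- cell_adjacency(pam, "rook")
  rowi <- (pam$cells - 1) %/% 6
  coli <- (pam$cells - 1) %% 6
  checker <- ifelse((rowi + coli) %% 2 == 0, 1, -1)
  res <- morans_i(checker, W, n_perm = 99, seed = 1)
  expect_equal(res$I, -1)
  grad <- morans_i(as.numeric(coli), W, n_perm = 999, seed = 2)
  expect_gt(grad$I, 0)
  expect_lte(grad$p_value, 0.001)
  expect_error(morans_i(rep(1, 36), W), "zero variance")
})

test_that("kriging interpolates exactly and handles degenerate fields", {
  set.seed(6)
  pts <- cbind(runif(25, 0, 10), runif(25, 0, 10))
  vals <- sin(pts[, 1] / 2) + 0.1 * rnorm(25)
  kr <- krige_axis(pts, vals, grid_spec(c(0, 0, 10, 10), 0.5))
  expect_lt(max(abs(kr$predict(pts) - vals)), 1e-6)
  expect_true(all(kr$variance$values >= 0))
  # constant observations give a constant surface
  kc <- krige_axis(pts, rep(3.2, 25), grid_spec(c(0, 0, 10, 10), 1))
  expect_true(all(kc$prediction$values == 3.2))
  # far beyond the range, the predictor collapses to the kriged mean
  far_pts <- cbind(seq(0, 36, by = 4), rep(0, 10))  # mutually > 400 km apart
  set.seed(7); far_vals <- rnorm(10)
  kf <- krige_axis(far_pts, far_vals, grid_spec(c(0, 0, 40, 4), 2),
                   params = list(nugget = 0.01, sill = 1, range_km = 50))
  expect_equal(kf$predict(cbind(120, 60)), mean(far_vals), tolerance = 0.01)
})

test_that("rgb composite rescales bands independently", {
  g <- grid_spec(c(0, 0, 4, 4), 1)
  s1 <- kernel_surface_new(g, matrix(seq(0, 15), 4, 4))
  s2 <- kernel_surface_new(g, matrix(seq(30, 0, length.out = 16), 4, 4))
  s3 <- kernel_surface_new(g, matrix(5, 4, 4))
  expect_warning(rgb <- rgb_composite(s1, s2, s3), "constant band")
  expect_equal(range(rgb[, , 1]), c(0, 255))
  expect_equal(range(rgb[, , 2]), c(0, 255))
  expect_true(all(rgb[, , 3] == 128))
  # permuting axes permutes bands
  expect_warning(rgb2 <- rgb_composite(s2, s1, s3), "constant band")
  expect_equal(rgb2[, , 1], rgb[, , 2])
  expect_equal(rgb2[, , 2], rgb[, , 1])
})

test_that("composition pipeline is reproducible end to end", {
  sc <- scenario_presets("one_river")
  gen <- generate_scenario(sc)
  pam <- filter_cells_by_records(
    build_presence_matrix(gen$records, grid_spec(sc$extent, 2)), 10)
  r <- grid_spec(sc$extent, 1)
  p1 <- composition_pipeline(pam, r, n_starts = 5, n_perm = 99, seed = 3)
  p2 <- composition_pipeline(pam, r, n_starts = 5, n_perm = 99, seed = 3)
  expect_identical(p1$ordination$scores, p2$ordination$scores)
  expect_identical(p1$surfaces[[1]]$prediction$values,
                   p2$surfaces[[1]]$prediction$values)
  expect_identical(vapply(p1$moran, `[[`, numeric(1), "p_value"),
                   vapply(p2$moran, `[[`, numeric(1), "p_value"))
  expect_equal(dim(p1$rgb), c(r$n_rows, r$n_cols, 3))
})

test_that("turnover dominates total dissimilarity on a river scenario", {
  sc <- scenario_presets("one_river")
  gen <- generate_scenario(sc)
  pam <- filter_cells_by_records(
    build_presence_matrix(gen$records, grid_spec(sc$extent, 2)), 10)
  pb <- partition_beta(pam)
  lower <- lower.tri(pb$total)
  cor_turn <- cor(pb$total[lower], pb$turnover[lower])
  cor_nest <- cor(pb$total[lower], pb$nestedness[lower])
  expect_gt(cor_turn, cor_nest)
})

test_that("the sharpest kriged composition step sits on the planted river", {
  hits <- 0
  for (sd in 11:15) {
    sc <- scenario_presets("one_river", seed = sd)
    gen <- generate_scenario(sc)
    pam <- filter_cells_by_records(
      build_presence_matrix(gen$records, grid_spec(sc$extent, 2)), 10)
    d <- bray_curtis_matrix(pam)
    ord <- nmds(d, k = 2, n_starts = 5, seed = sd)
    ctr <- cell_centroid(pam$grid, pam$cells)
    # largest absolute axis-1 difference between east-west adjacent cells
    best <- 0; best_straddles <- FALSE
    for (a in seq_along(pam$cells)) {
      nb <- which(abs(ctr$lon - ctr$lon[a]) == 2 & ctr$lat == ctr$lat[a])
      for (b in nb) {
        diffv <- abs(ord$scores[a, 1] - ord$scores[b, 1])
        if (diffv > best) {
          best <- diffv
          best_straddles <- (ctr$lon[a] < -60) != (ctr$lon[b] < -60)
        }
      }
    }
    hits <- hits + best_straddles
  }
  expect_gte(hits, 4)  # at least 4 of 5 seeds
})
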