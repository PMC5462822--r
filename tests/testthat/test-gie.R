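test_that("range categories partition the axis with the stated bounds", {
  cats <- range_categories()
  expect_equal(nrow(cats), 11L)
  expect_equal(cats$lower_km[-1], cats$upper_km[-11])
  expect_equal(assign_category(c(0, 100, 150, 200.5, 2050)),
               c(1L, 1L, 2L, 3L, 11L))
  expect_warning(over <- assign_category(3000), "clamped")
  expect_equal(over, 11L)
})

test_that("quartic kernel has compact support, unit mass and additivity", {
  r <- grid_spec(c(-2, -2, 2, 2), 0.1)
  s <- kernel_surface(cbind(0, 0), 100, r)
  pix <- cell_centroid(r)
  d <- haversine_km(c(0, 0), cbind(pix$lon, pix$lat))
  far <- matrix(d, r$n_rows, r$n_cols, byrow = TRUE) >= 100
  expect_true(all(s$values[far] == 0))
  expect_equal(sum(s$values * cell_area_km2(r)), 1, tolerance = 0.02)
  s2 <- kernel_surface(cbind(0.5, 0.5), 100, r)
  both <- kernel_surface(rbind(c(0, 0), c(0.5, 0.5)), 100, r)
  expect_equal(both$values, s$values + s2$values)
  expect_error(kernel_surface(cbind(0, 0), -5, r), "positive")
})

test_that("consensus standardizes per category and is scale equivariant", {
  r <- grid_spec(c(-5, -5, 5, 5), 0.25)
  sm <- data.frame(taxon_id = c("a", "b", "c"),
                   centroid_lon = c(0, 1, -1), centroid_lat = c(0, 1, -1),
                   max_dist_km = c(150, 160, 155), n_records = 5)
  g1 <- gie_consensus(sm, r)
  expect_equal(length(g1$category_surfaces), 1L)
  expect_equal(max(g1$consensus$values), 1)
  # two categories with identical centroid sets stack to 2 at the peak
  sm2 <- rbind(sm, transform(sm, taxon_id = paste0(taxon_id, "2"),
                             max_dist_km = 350))
  g2 <- gie_consensus(sm2, r)
  expect_equal(length(g2$category_surfaces), 2L)
  expect_lte(abs(max(g2$consensus$values) - 2) , 0.05)
  # multiplying any layer by a constant is absorbed by standardization
  g3 <- gie_consensus(sm2, r, bandwidths = range_categories()$upper_km)
  expect_equal(g3$consensus$values, g2$consensus$values)
})

test_that("bare-surface delineation follows the plain threshold rule", {
  g <- grid_spec(c(0, 0, 10, 10), 0.5)
  zero <- kernel_surface_new(g, 0)
  expect_length(delineate_aoes(zero), 0L)
  # one Gaussian-like peak
  pix <- cell_centroid(g)
  v1 <- matrix(exp(-((pix$lon - 5)^2 + (pix$lat - 5)^2)), g$n_rows,
               g$n_cols, byrow = TRUE)
  one <- delineate_aoes(kernel_surface_new(g, v1))
  expect_length(one, 1L)
  peak_cell <- cell_index(g, 5.25, 5.25)
  expect_true(peak_cell %in% one[[1]]$cells)
  # two peaks of height 1 with a deep valley split at threshold 0.3
  v2 <- matrix(pmax(exp(-((pix$lon - 2)^2 + (pix$lat - 5)^2) / 0.5),
                    exp(-((pix$lon - 8)^2 + (pix$lat - 5)^2) / 0.5)),
               g$n_rows, g$n_cols, byrow = TRUE)
  two <- delineate_aoes(kernel_surface_new(g, v2), 0.3)
  expect_length(two, 2L)
})

test_that("surface correlation behaves as Pearson r", {
  g <- grid_spec(c(0, 0, 5, 5), 0.5)
  s <- smoothed_noise_surface(g, 1, seed = 4)
  expect_equal(surface_correlation(s, s), 1)
  anti <- kernel_surface_new(g, max(s$values) - s$values)
  expect_equal(surface_correlation(s, anti), -1)
  s2 <- smoothed_noise_surface(g, 1, seed = 5)
  expect_equal(surface_correlation(s, s2), surface_correlation(s2, s))
  expect_error(surface_correlation(s, kernel_surface_new(g, 1)), "constant")
})

test_that("category admission rejects saturated and chance-level layers", {
  sc <- scenario_presets("three_aoes")
  gen <- generate_scenario(sc)
  sm <- suppressWarnings(taxon_range_summary(gen$records))
  gie <- suppressWarnings(gie_consensus(sm, grid_spec(sc$extent, 0.5)))
  adm <- category_concentration_test(gie)
  expect_true(all(c("contrast", "stacking", "p_value") %in% names(adm)))
  # the largest range classes saturate the window: never admitted
  expect_false(any(adm$admitted[adm$category >= 10]))
  # at least one endemic-scale class carries the planted signal
  expect_true(any(adm$admitted[adm$category <= 6]))
})

test_that("jaccard and polygon rasterization agree on simple shapes", {
  g <- grid_spec(c(0, 0, 10, 10), 1)
  sq <- rasterize_polygon(g, square_poly(2, 2, 4))
  expect_equal(length(sq), 16L)  # 4 x 4 cells have centroids inside
  expect_equal(jaccard_cells(sq, sq), 1)
  expect_equal(jaccard_cells(sq, rasterize_polygon(g, square_poly(2, 2, 2))),
               4 / 16)
})
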