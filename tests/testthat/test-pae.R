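make_cm <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  pam <- pam_from_matrix(m, grid_spec(c(0, 0, max(3, nrow(m)), 1), 1))
  suppressMessages(build_character_matrix(pam))
}

make_cm_msg <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  pam <- pam_from_matrix(m, grid_spec(c(0, 0, max(3, nrow(m)), 1), 1))
  build_character_matrix(pam)
}

test_that("character matrix appends an all-absent outgroup and flags", {
  m <- rbind(c(1, 0, 1), c(0, 1, 1), c(0, 0, 1))
  expect_message(cm <- make_cm_msg(m), "invariant")
  expect_equal(unname(cm$mat["outgroup", ]), c(0L, 0L))
  expect_equal(cm$pruned, "sp3")           # present in every cell
  expect_setequal(cm$uninformative, c("sp1", "sp2"))  # singletons kept
  pam_small <- pam_from_matrix(rbind(c(1, 0), c(0, 1)),
                               grid_spec(c(0, 0, 3, 1), 1))
  expect_error(suppressMessages(build_character_matrix(pam_small)),
               "too few")
})

test_that("Fitch lengths match hand-computed cases", {
  m <- rbind(cell_1 = c(1, 1), cell_2 = c(1, 0),
             cell_3 = c(0, 1), cell_4 = c(0, 0))
  cm <- make_cm(m)
  # ((1,2),(3,4)) rooted on the outgroup
  tr <- ape::read.tree(
    text = "(outgroup,((cell_1,cell_2),(cell_3,cell_4)));")
  # sp1 single origin on the (1,2) clade: 1 step
  # sp2 present in cell_1 and cell_3, opposite sides: 2 steps
  expect_equal(fitch_length(tr, cm), 3L)
  tr2 <- ape::read.tree(
    text = "(outgroup,((cell_1,cell_3),(cell_2,cell_4)));")
  expect_equal(fitch_length(tr2, cm), 3L)  # roles of sp1/sp2 swap
  expect_error(fitch_length(ape::read.tree(text = "(a,(b,c));"), cm),
               "do not match")
})

test_that("Fitch length is invariant to character order and relabeling", {
  set.seed(21)
  m <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12)
  cm <- make_cm(m)
  tr <- ape::read.tree(text =
    "(outgroup,((cell_1,cell_2),(cell_3,(cell_4,cell_5))));")
  base <- fitch_length(tr, cm)
  perm <- sample(ncol(cm$mat))
  cm_perm <- cm
  cm_perm$mat <- cm$mat[, perm, drop = FALSE]
  expect_equal(fitch_length(tr, cm_perm), base)
  # taxon relabeling: permute the cell names consistently
  relab <- cm
  map <- c(cell_1 = "cell_3", cell_2 = "cell_4", cell_3 = "cell_5",
           cell_4 = "cell_1", cell_5 = "cell_2", outgroup = "outgroup")
  rownames(relab$mat) <- unname(map[rownames(cm$mat)])
  tr_re <- tr
  tr_re$tip.label <- unname(map[tr$tip.label])
  expect_equal(fitch_length(tr_re, relab), base)
})

test_that("a perfectly hierarchical matrix yields its single tree", {
  m <- rbind(
    cell_1 = c(1, 1, 1, 0, 0),
    cell_2 = c(1, 1, 0, 0, 0),
    cell_3 = c(1, 0, 0, 0, 0),
    cell_4 = c(0, 0, 0, 1, 1),
    cell_5 = c(0, 0, 0, 1, 0))
  cm <- make_cm(m)
  res <- heuristic_search(cm, n_ras = 10, seed = 2)
  expect_equal(res$best_length, ncol(cm$mat))  # one step per character
  expect_length(res$shortest_trees, 1L)
  expect_true("cell_1+cell_2" %in% names(res$supported_clades))
  expect_true("cell_4+cell_5" %in% names(res$supported_clades))
  # rerun with the same seed reproduces the same tree set
  res2 <- heuristic_search(cm, n_ras = 10, seed = 2)
  expect_equal(lapply(res$shortest_trees, ape::write.tree),
               lapply(res2$shortest_trees, ape::write.tree))
})

test_that("non-homoplastic support excludes characters needing 2 steps", {
  m <- rbind(
    cell_1 = c(1, 1, 1, 0),
    cell_2 = c(1, 1, 0, 0),
    cell_3 = c(1, 0, 0, 1),
    cell_4 = c(0, 0, 1, 1),   # sp3 homoplastic: cells 1 and 4 are apart
    cell_5 = c(0, 0, 0, 1))
  cm <- make_cm(m)
  res <- heuristic_search(cm, n_ras = 20, seed = 3)
  chars <- unlist(lapply(res$supported_clades, `[[`, "characters"))
  expect_false("sp3" %in% chars)
})

test_that("heuristic search equals the exhaustive oracle on small instances", {
  set.seed(5)
  agree <- 0
  for (i in 1:25) {
    m <- matrix(rbinom(6 * 20, 1, 0.4), 6, 20)
    cm <- make_cm(m)
    h <- heuristic_search(cm, n_ras = 5, seed = i)
    ex <- exhaustive_search(cm)
    agree <- agree + (h$best_length == ex$best_length)
  }
  expect_gte(agree, 24)
})

test_that("constrained searches cost steps only for incompatible groups", {
  m <- rbind(
    cell_1 = c(1, 1, 1, 1, 1, 0, 0, 1, 0),
    cell_2 = c(1, 1, 1, 1, 1, 0, 0, 0, 0),
    cell_3 = c(1, 1, 1, 1, 0, 1, 0, 0, 0),
    cell_4 = c(0, 0, 0, 0, 0, 0, 1, 1, 1),
    cell_5 = c(0, 0, 0, 0, 0, 0, 1, 0, 1),
    cell_6 = c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  cm <- make_cm(m)
  h <- heuristic_search(cm, n_ras = 20, seed = 1)
  # forcing the two most dissimilar cells together costs extra steps;
  # compare against monophyly-filtered enumeration
  cs <- constrained_search(cm, list(g = c("cell_3", "cell_4")), seed = 2,
                           n_ras = 5, unconstrained = h)
  trees <- phangorn::allTrees(7, rooted = FALSE,
                              tip.label = rownames(cm$mat))
  dat <- endemap:::as_phydat(cm)
  lens <- phangorn::parsimony(trees, dat, method = "fitch")
  okc <- vapply(seq_along(trees), function(k)
    ape::is.monophyletic(ape::root(trees[[k]], "outgroup",
                                   resolve.root = TRUE),
                         c("cell_3", "cell_4")), logical(1))
  expect_equal(cs$constrained_length, min(lens[okc]))
  expect_gt(cs$extra_steps, 0)
  expect_true(ape::is.monophyletic(cs$constrained_tree,
                                   c("cell_3", "cell_4")))
  # constraints matching real clades are free
  cs2 <- constrained_search(cm, list(g = c("cell_1", "cell_2", "cell_3")),
                            seed = 3, n_ras = 5, unconstrained = h)
  expect_equal(cs2$extra_steps, 0L)
  # a single group holding every cell is vacuous
  cs3 <- constrained_search(cm, list(g = rownames(m)), seed = 4, n_ras = 3,
                            unconstrained = h)
  expect_equal(cs3$extra_steps, 0L)
  expect_error(constrained_search(cm, list(a = c("cell_1", "cell_2"),
                                           b = c("cell_2", "cell_3")),
                                  seed = 1),
               "overlapping")
})

test_that("gridded planted areas surface as supported clades", {
  sc <- scenario_presets("three_aoes")
  gen <- generate_scenario(sc)
  pam <- build_presence_matrix(gen$records, grid_spec(sc$extent, 2))
  # keep the analysis desk-scale: only cells with clear sampling
  pam <- filter_cells_by_records(pam, 10)
  cm <- suppressMessages(build_character_matrix(pam))
  res <- heuristic_search(cm, n_ras = 10, seed = 42)
  # map each supported clade to planted polygons: count clades whose
  # cells all lie inside one polygon
  polys <- lapply(sc$planted_aoes, `[[`, "polygon")
  cells_of <- function(clade) as.integer(sub("cell_", "", clade$cells))
  inside <- function(cells, poly) {
    ctr <- cell_centroid(pam$grid, cells)
    all(sp::point.in.polygon(ctr$lon, ctr$lat, poly[, 1], poly[, 2]) > 0)
  }
  hit <- logical(3)
  for (cl in res$supported_clades) {
    for (ai in 1:3) if (inside(cells_of(cl), polys[[ai]])) hit[ai] <- TRUE
  }
  expect_gte(sum(hit), 2)
})
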