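#' Character matrix for Parsimony Analysis of Endemicity
#'
#' Treats grid cells as terminals and taxa presences as binary characters,
#' appending an all-absent hypothetical outgroup used to root the trees.
#' Characters invariant across the ingroup cells (taxa present in every
#' cell) are pruned and logged; parsimony-uninformative characters
#' (singleton presences) are kept but flagged.
#'
#' @param pam a `pam`, typically on a two-degree grid.
#' @param outgroup label for the all-absent outgroup row.
#' @return list of class `character_matrix`: `mat` (cells + outgroup x
#'   characters, 0/1), `outgroup`, `pruned` (invariant characters),
#'   `uninformative` (flagged characters).
#' @export
build_character_matrix <- function(pam, outgroup = "outgroup") {
  if (length(pam$cells) < 3L) stop("too few taxa: need at least 3 cells")
  m <- pam$m
  invariant <- colSums(m) == nrow(m) | colSums(m) == 0
  pruned <- colnames(m)[invariant]
  if (any(invariant)) {
    message(sum(invariant), " invariant character(s) pruned: ",
            paste(utils::head(pruned, 5), collapse = ", "),
            if (length(pruned) > 5) ", ...")
    m <- m[, !invariant, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("no variable characters")
  mat <- rbind(m, 0L)
  rownames(mat) <- c(rownames(m), outgroup)
  uninform <- colnames(m)[colSums(m) <= 1]
  structure(list(mat = mat, outgroup = outgroup, pruned = pruned,
                 uninformative = uninform),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d terminals (incl. outgroup) x %d characters (%d uninformative, %d pruned)\n",
              nrow(x$mat), ncol(x$mat), length(x$uninformative),
              length(x$pruned)))
  invisible(x)
}

as_phydat <- function(cm) {
  m <- cm$mat
  mode(m) <- "character"
  phangorn::phyDat(m, type = "USER", levels = c("0", "1"))
}

#' Fitch parsimony length of a tree
#'
#' @param tree a `phylo` whose tip labels match the matrix terminals.
#' @param cm a `character_matrix`.
#' @return integer number of Fitch steps.
#' @export
fitch_length <- function(tree, cm) {
  if (!setequal(tree$tip.label, rownames(cm$mat)))
    stop("tree tips do not match matrix terminals")
  as.integer(phangorn::fitch(tree, as_phydat(cm)))
}

root_on_outgroup <- function(tree, outgroup) {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::reorder.phylo(tr, "cladewise")
}

#' Heuristic parsimony search
#'
#' Desk-scale tree search: `n_ras` random-addition-sequence starting trees,
#' each refined to a local optimum by branch swapping (NNI, or SPR by
#' default), retaining all distinct topologies at the best length found.
#' Deterministic given the seed.
#'
#' @param cm a `character_matrix`.
#' @param n_ras number of random-addition replicates (default 100).
#' @param swap rearrangement used by the swapper: `"SPR"` (default,
#'   includes NNI moves) or `"NNI"`.
#' @param seed integer seed.
#' @param keep_max cap on the number of retained shortest trees.
#' @return list of class `pae_result`: `shortest_trees` (multiPhylo,
#'   rooted on the outgroup), `best_length`, `consensus` (strict),
#'   `supported_clades` (see [supported_clades()]), `n_ras`.
#' @export
heuristic_search <- function(cm, n_ras = 100, swap = c("SPR", "NNI"),
                             seed = 1, keep_max = 10000) {
  swap <- match.arg(swap)
  dat <- as_phydat(cm)
  set.seed(seed)
  best_len <- Inf
  found <- list()
  for (rep in seq_len(n_ras)) {
    tr0 <- phangorn::random.addition(dat)
    tr <- suppressMessages(
      phangorn::optim.parsimony(tr0, dat, method = "fitch",
                                rearrangements = swap, trace = 0))
    len <- attr(tr, "pscore")
    if (is.null(len)) len <- phangorn::fitch(tr, dat)
    len <- as.integer(len)
    if (len < best_len) {
      best_len <- len
      found <- list(tr)
    } else if (len == best_len && length(found) < keep_max) {
      found[[length(found) + 1L]] <- tr
    }
  }
  finish_search(found, best_len, cm, n_ras)
}

finish_search <- function(found, best_len, cm, n_ras) {
  rooted <- lapply(found, root_on_outgroup, outgroup = cm$outgroup)
  class(rooted) <- "multiPhylo"
  rooted <- unique(rooted, use.edge.length = FALSE, use.tip.label = TRUE)
  cons <- if (length(rooted) > 1L)
    ape::consensus(rooted, p = 1, rooted = TRUE) else rooted[[1]]
  out <- list(shortest_trees = rooted, best_length = as.integer(best_len),
              consensus = cons, n_ras = n_ras)
  out$supported_clades <- supported_clades(out, cm)
  class(out) <- "pae_result"
  out
}

#' @export
print.pae_result <- function(x, ...) {
  cat(sprintf("parsimony result: %d shortest tree(s) of length %d; %d clade(s) with non-homoplastic support\n",
              length(x$shortest_trees), x$best_length,
              length(x$supported_clades)))
  invisible(x)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (feasible up to about ten
#' terminals) and returns the exact minimum length.  Used as the oracle
#' against which the heuristic search is validated.
#'
#' @param cm a `character_matrix`.
#' @return list: `best_length`, `shortest_trees` (rooted on the outgroup),
#'   `n_evaluated`.
#' @export
exhaustive_search <- function(cm) {
  labels <- rownames(cm$mat)
  if (length(labels) > 10L) stop("exhaustive search limited to 10 terminals")
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  dat <- as_phydat(cm)
  lens <- phangorn::parsimony(trees, dat, method = "fitch")
  best <- min(lens)
  found <- trees[lens == best]
  rooted <- lapply(found, root_on_outgroup, outgroup = cm$outgroup)
  class(rooted) <- "multiPhylo"
  list(best_length = as.integer(best),
       shortest_trees = unique(rooted, use.edge.length = FALSE),
       n_evaluated = length(trees))
}

clade_tip_sets <- function(tree) {
  # leaf sets of all internal nodes, cladewise
  nt <- length(tree$tip.label)
  sets <- list()
  for (nd in (nt + 1):(nt + tree$Nnode)) {
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, nd, "tips"))]
    sets[[length(sets) + 1L]] <- sort(tips)
  }
  unique(sets)
}

#' Clades with non-homoplastic character support
#'
#' Reports the clades of the strict consensus supported by at least one
#' character whose presences coincide exactly with the clade's terminals
#' and which requires a single step on every shortest tree (a
#' non-homoplastic synapomorphy).
#'
#' @param result a `pae_result` (or a list with `consensus` and
#'   `shortest_trees`).
#' @param cm the `character_matrix` the search used.
#' @return named list: clade label -> list(`cells`, `characters`).
#' @export
supported_clades <- function(result, cm) {
  dat <- as_phydat(cm)
  # per-character steps on each shortest tree
  steps <- vapply(result$shortest_trees, function(tr) {
    s <- phangorn::fitch(tr, dat, site = "site")
    as.numeric(s)[attr(dat, "index")]
  }, numeric(ncol(cm$mat)))
  if (is.null(dim(steps))) steps <- matrix(steps, ncol = 1)
  nonhomoplastic <- rowSums(steps == 1) == ncol(steps)
  presences <- apply(cm$mat == 1L, 2, function(col)
    sort(rownames(cm$mat)[col]), simplify = FALSE)
  sets <- clade_tip_sets(result$consensus)
  out <- list()
  for (s in sets) {
    if (cm$outgroup %in% s) next           # clades of the ingroup only
    if (length(s) < 2L) next
    chars <- which(nonhomoplastic &
                     vapply(presences, identical, logical(1), y = s))
    if (length(chars)) {
      out[[paste(s, collapse = "+")]] <-
        list(cells = s, characters = colnames(cm$mat)[chars])
    }
  }
  out
}

# ---- constrained search ------------------------------------------------

# insert a new tip into `tree` splitting edge `eidx`; edge lengths ignored
insert_tip <- function(tree, tip_label, eidx) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  map <- function(x) ifelse(x <= nt, x, x + 1L)  # internals shift by one
  e <- apply(tree$edge, 2, map)
  new_tip <- nt + 1L
  new_int <- nt + 1L + nn + 1L
  p <- e[eidx, 1]; ch <- e[eidx, 2]
  e[eidx, ] <- c(p, new_int)
  e <- rbind(e, c(new_int, ch), c(new_int, new_tip))
  out <- list(edge = e, tip.label = c(tree$tip.label, tip_label),
              Nnode = nn + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

# greedy rooted RAS over a character matrix subset; labels shuffled by caller
grow_tree_greedy <- function(labels, dat) {
  if (length(labels) == 1L) return(labels)      # degenerate: a bare tip
  tr <- ape::read.tree(text = sprintf("(%s,%s);", labels[1], labels[2]))
  for (lb in labels[-(1:2)]) {
    scores <- vapply(seq_len(nrow(tr$edge)), function(ei)
      as.numeric(phangorn::fitch(insert_tip(tr, lb, ei), dat)), numeric(1))
    tr <- insert_tip(tr, lb, which.min(scores))
  }
  tr
}

# constraint-respecting random-addition tree: each group is grown as its own
# subtree and grafted into a skeleton in which the group is a single
# placeholder terminal (scored on the union of its members' presences), so
# every group is monophyletic by construction
ras_constrained <- function(cm, groups, dat) {
  labels <- rownames(cm$mat)
  flat <- unlist(groups)
  free <- setdiff(labels, c(cm$outgroup, flat))
  placeholders <- sprintf("CONSTRAINTGRP%d", seq_along(groups))
  sub_newick <- character(length(groups))
  for (gi in seq_along(groups)) {
    g <- sample(groups[[gi]])
    if (length(g) == 1L) { sub_newick[gi] <- g; next }
    dat_g <- phangorn::phyDat(
      {m <- cm$mat[g, , drop = FALSE]; mode(m) <- "character"; m},
      type = "USER", levels = c("0", "1"))
    tr_g <- grow_tree_greedy(g, dat_g)
    sub_newick[gi] <- sub(";$", "", ape::write.tree(tr_g))
  }
  red <- rbind(cm$mat[c(cm$outgroup, free), , drop = FALSE],
               do.call(rbind, lapply(groups, function(g)
                 as.integer(colSums(cm$mat[g, , drop = FALSE]) > 0))))
  rownames(red) <- c(cm$outgroup, free, placeholders)
  mode(red) <- "character"
  dat_red <- phangorn::phyDat(red, type = "USER", levels = c("0", "1"))
  ord <- c(cm$outgroup, sample(c(free, placeholders)))
  sk <- if (length(ord) == 2L)
    sprintf("(%s,%s);", ord[1], ord[2])
  else {
    tr0 <- ape::read.tree(text = sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3]))
    for (lb in ord[-(1:3)]) {
      scores <- vapply(seq_len(nrow(tr0$edge)), function(ei)
        as.numeric(phangorn::fitch(insert_tip(tr0, lb, ei), dat_red)),
        numeric(1))
      tr0 <- insert_tip(tr0, lb, which.min(scores))
    }
    ape::write.tree(tr0)
  }
  for (gi in seq_along(groups))
    sk <- sub(paste0("\\b", placeholders[gi], "\\b"), sub_newick[gi], sk)
  ape::read.tree(text = sk)
}

groups_monophyletic <- function(tree, groups, outgroup) {
  rt <- root_on_outgroup(tree, outgroup)
  all(vapply(groups, function(g) {
    g <- intersect(g, tree$tip.label)
    length(g) < 2L || ape::is.monophyletic(rt, g)
  }, logical(1)))
}

#' Parsimony search under monophyly constraints
#'
#' Repeats the tree search while forcing each group of cells to be
#' monophyletic (e.g. cells grouped by candidate interfluve areas of
#' endemism), and reports the extra steps the constraint costs relative to
#' the unconstrained shortest trees.  The constrained search uses
#' constraint-respecting random addition followed by NNI swapping filtered
#' to moves that keep every group monophyletic.
#'
#' @param cm a `character_matrix`.
#' @param groups named list of cell-label vectors; must be disjoint.
#' @param seed integer seed.
#' @param n_ras random-addition replicates for the constrained search.
#' @param unconstrained optional `pae_result` to reuse as the unconstrained
#'   baseline; computed with the same seed when missing.
#' @return list of class `constrained_result`: `constrained_length`,
#'   `best_length`, `extra_steps`, `constrained_tree`, `groups`.
#' @export
constrained_search <- function(cm, groups, seed = 1, n_ras = 20,
                               unconstrained = NULL) {
  labels <- rownames(cm$mat)
  flat <- unlist(groups)
  if (anyDuplicated(flat)) stop("overlapping groups: contradictory constraints")
  if (!all(flat %in% setdiff(labels, cm$outgroup)))
    stop("groups contain unknown cells (or the outgroup)")
  if (is.null(unconstrained))
    unconstrained <- heuristic_search(cm, n_ras = max(n_ras, 20), seed = seed)
  dat <- as_phydat(cm)
  set.seed(seed + 1L)
  best_len <- Inf
  best_tree <- NULL
  for (rep in seq_len(n_ras)) {
    tr <- ras_constrained(cm, groups, dat)
    len <- as.numeric(phangorn::fitch(tr, dat))
    repeat {
      nb <- phangorn::nni(tr)
      improved <- FALSE
      for (kk in seq_along(nb)) {
        cand <- nb[[kk]]  # [[ restores tip labels from compressed multiPhylo
        lc <- as.numeric(phangorn::fitch(cand, dat))
        if (lc < len && groups_monophyletic(cand, groups, cm$outgroup)) {
          # canonicalize before the next round of rearrangements
          tr <- ape::read.tree(text = ape::write.tree(cand))
          len <- lc; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (len < best_len) {
      best_len <- len
      best_tree <- tr
    }
  }
  structure(list(
    constrained_length = as.integer(best_len),
    best_length = unconstrained$best_length,
    extra_steps = as.integer(best_len) - unconstrained$best_length,
    constrained_tree = root_on_outgroup(best_tree, cm$outgroup),
    groups = groups, unconstrained = unconstrained),
    class = "constrained_result")
}

#' @export
print.constrained_result <- function(x, ...) {
  cat(sprintf("constrained length %d vs unconstrained %d: %d extra step(s)\n",
              x$constrained_length, x$best_length, x$extra_steps))
  invisible(x)
}

#' Export a character matrix in TNT format
#'
#' @param cm a `character_matrix`.
#' @param path output file.
#' @export
write_tnt <- function(cm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("xread",
               sprintf("'%s'", "binary presence/absence matrix"),
               sprintf("%d %d", ncol(cm$mat), nrow(cm$mat))), con)
  for (i in seq_len(nrow(cm$mat)))
    writeLines(sprintf("%s %s", gsub("[^A-Za-z0-9_]", "_", rownames(cm$mat)[i]),
                       paste(cm$mat[i, ], collapse = "")), con)
  writeLines(c(";", "proc /;"), con)
  invisible(path)
}

#' Export a character matrix as NEXUS
#'
#' @param cm a `character_matrix`.
#' @param path output file.
#' @export
write_nexus_matrix <- function(cm, path) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- gsub("[^A-Za-z0-9_]", "_", rownames(cm$mat))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cm$mat),
                       ncol(cm$mat)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX"), con)
  for (i in seq_len(nrow(cm$mat)))
    writeLines(sprintf("    %s %s", nm[i], paste(cm$mat[i, ], collapse = "")),
               con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
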