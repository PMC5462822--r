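#' Delaunay/Voronoi network over cell centroids
#'
#' Builds the Delaunay triangulation of the centroids, attaches the
#' corresponding dissimilarity to every edge, and records for each
#' Delaunay edge its dual Voronoi (Thiessen) segment, clipped to the
#' bounding box inflated by one cell.
#'
#' @param centroids two-column matrix or data.frame of (lon, lat).
#' @param d a `dissim` matrix over the same points (same order).
#' @param inflate bounding-box inflation in degrees (default 1).
#' @return list of class `spatial_network`: `nodes` (data.frame), `edges`
#'   (data.frame with endpoints `i`, `j`, `dissimilarity`, the dual
#'   Voronoi segment `vx1`,`vy1`,`vx2`,`vy2` and boundary flags
#'   `bp1`,`bp2`).
#' @export
build_network <- function(centroids, d, inflate = 1) {
  pts <- as.matrix(centroids)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  dm <- as.matrix(d)
  stopifnot(nrow(dm) == n)
  ctr <- sweep(pts, 2, colMeans(pts))
  if (svd(ctr)$d[2] < 1e-9 * max(svd(ctr)$d[1], 1))
    stop("degenerate triangulation: all points are collinear")
  rw <- c(min(pts[, 1]) - inflate, max(pts[, 1]) + inflate,
          min(pts[, 2]) - inflate, max(pts[, 2]) + inflate)
  dd <- tryCatch(deldir::deldir(pts[, 1], pts[, 2], rw = rw),
                 error = function(e) stop("degenerate triangulation: ",
                                          conditionMessage(e)))
  if (is.null(dd$delsgs) || nrow(dd$delsgs) == 0L)
    stop("degenerate triangulation: no Delaunay edges (collinear points?)")
  del <- dd$delsgs
  dir <- dd$dirsgs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mdir <- match(key(del$ind1, del$ind2), key(dir$ind1, dir$ind2))
  edges <- data.frame(
    i = pmin(del$ind1, del$ind2),
    j = pmax(del$ind1, del$ind2),
    dissimilarity = dm[cbind(del$ind1, del$ind2)],
    vx1 = dir$x1[mdir], vy1 = dir$y1[mdir],
    vx2 = dir$x2[mdir], vy2 = dir$y2[mdir],
    bp1 = dir$bp1[mdir], bp2 = dir$bp2[mdir]
  )
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(lon = pts[, 1], lat = pts[, 2]),
                 edges = edges, rw = rw),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("spatial network: %d nodes, %d Delaunay edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Monmonier maximum-difference barriers
#'
#' Traces barriers along the Voronoi diagram of the network: each barrier
#' seeds at the not-yet-crossed Delaunay edge with the largest
#' dissimilarity and grows from both ends of that edge's dual Voronoi
#' segment, at every step crossing the adjacent not-yet-crossed Delaunay
#' edge of greatest dissimilarity.  A growing tip stops when it reaches
#' the network boundary, a vertex already used by an earlier barrier, or
#' its own path.  Ties are broken deterministically by the lowest
#' `(i, j)` endpoint pair.  No Delaunay edge is crossed twice across
#' barriers, so seed-edge dissimilarity is non-increasing with rank.
#'
#' @param network a `spatial_network`.
#' @param n_barriers number of barriers to trace (default 15).
#' @return list of class `barrier_set`; each barrier has `rank`,
#'   `seed_dissimilarity`, `crossed_edges` (data.frame, in crossing
#'   order), `path` (matrix of Voronoi vertices along the barrier),
#'   `total_strength`.
#' @export
monmonier <- function(network, n_barriers = 15) {
  ed <- network$edges
  ne <- nrow(ed)
  vkey <- function(x, y) sprintf("%.9f_%.9f", x, y)
  k1 <- vkey(ed$vx1, ed$vy1)
  k2 <- vkey(ed$vx2, ed$vy2)
  # edges whose dual segment was clipped away entirely act as dead ends
  nodual <- is.na(ed$vx1) | is.na(ed$vx2)
  k1[nodual] <- paste0("nodual_a_", which(nodual))
  k2[nodual] <- paste0("nodual_b_", which(nodual))
  ed$bp1[nodual] <- TRUE
  ed$bp2[nodual] <- TRUE
  verts <- unique(c(k1, k2))
  v1 <- match(k1, verts)
  v2 <- match(k2, verts)
  # incidence: Voronoi vertex -> Delaunay edges whose dual meets it
  inc <- split(rep(seq_len(ne), 2), c(v1, v2))
  boundary_vertex <- rep(FALSE, length(verts))
  boundary_vertex[v1[ed$bp1]] <- TRUE
  boundary_vertex[v2[ed$bp2]] <- TRUE
  vcoord <- matrix(NA_real_, length(verts), 2)
  numeric_v <- !startsWith(verts, "nodual")
  parts <- do.call(rbind, strsplit(verts[numeric_v], "_"))
  if (length(parts)) vcoord[numeric_v, ] <- as.numeric(parts)

  crossed <- rep(FALSE, ne)
  used_vertex <- rep(FALSE, length(verts))
  # deterministic ordering: dissimilarity desc, then lowest (i, j)
  pick <- function(cand) {
    cand[order(-ed$dissimilarity[cand], ed$i[cand], ed$j[cand])][1]
  }
  barriers <- list()
  for (b in seq_len(n_barriers)) {
    avail <- which(!crossed)
    if (!length(avail)) {
      warning("only ", length(barriers), " barriers available")
      break
    }
    seed <- pick(avail)
    crossed[seed] <- TRUE
    path_left <- integer(0)   # edges crossed extending from v1 side
    path_right <- integer(0)  # from v2 side
    grow <- function(start_vertex, own_path_vertices) {
      tip <- start_vertex
      out <- integer(0)
      visited <- own_path_vertices
      repeat {
        if (boundary_vertex[tip] || used_vertex[tip]) break
        if (tip %in% visited) break
        visited <- c(visited, tip)
        cand <- inc[[as.character(tip)]]
        cand <- cand[!crossed[cand]]
        if (!length(cand)) break
        nxt <- pick(cand)
        crossed[nxt] <<- TRUE
        out <- c(out, nxt)
        tip <- if (v1[nxt] == tip) v2[nxt] else v1[nxt]
      }
      list(edges = out, visited = visited, tip = tip)
    }
    gl <- grow(v1[seed], v2[seed])
    gr <- grow(v2[seed], c(v1[seed], gl$visited))
    crossed_edges <- c(rev(gl$edges), seed, gr$edges)
    # vertex chain from the left tip through the seed to the right tip
    chain <- integer(0)
    cur <- gl$tip
    for (e in crossed_edges) {
      chain <- c(chain, cur)
      cur <- if (v1[e] == cur) v2[e] else v1[e]
    }
    chain <- c(chain, cur)
    used_vertex[chain] <- TRUE
    barriers[[b]] <- list(
      rank = b,
      seed_dissimilarity = ed$dissimilarity[seed],
      crossed_edges = cbind(ed[crossed_edges, c("i", "j", "dissimilarity")],
                            order = seq_along(crossed_edges)),
      path = vcoord[chain, , drop = FALSE],
      total_strength = sum(ed$dissimilarity[crossed_edges])
    )
  }
  structure(barriers, class = "barrier_set")
}

#' @export
print.barrier_set <- function(x, ...) {
  cat(sprintf("%d Monmonier barrier(s)\n", length(x)))
  for (b in x)
    cat(sprintf("  rank %d: seed %.3f, %d edges crossed, strength %.2f\n",
                b$rank, b$seed_dissimilarity, nrow(b$crossed_edges),
                b$total_strength))
  invisible(x)
}

#' Fraction of a barrier's crossed edges that straddle a line
#'
#' For validation against planted rivers: the share of crossed Delaunay
#' edges whose endpoints fall on opposite sides of a polyline.
#'
#' @param barrier one element of a `barrier_set`.
#' @param network the `spatial_network` the barrier was traced on.
#' @param line two-column lon/lat polyline.
#' @return fraction in \[0, 1\].
#' @export
barrier_straddle_fraction <- function(barrier, network, line) {
  ce <- barrier$crossed_edges
  si <- side_of_polyline(line, network$nodes$lon[ce$i], network$nodes$lat[ce$i])
  sj <- side_of_polyline(line, network$nodes$lon[ce$j], network$nodes$lat[ce$j])
  mean(si != sj)
}
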