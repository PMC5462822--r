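#' Species-to-area fit index
#'
#' For a species' occupied cell set and a candidate area's cell set on the
#' same grid, computes `a` = percentage of the species' distribution
#' contained in the area, `b` = percentage of the area occupied by the
#' species, and the fit index `(a + b) / c` with `c = 200` (the sum of the
#' two percentage maxima), so the index lies in `[0, 1]` and equals 1 only
#' for a species exactly coincident with the area.
#'
#' @param species_cells integer vector of cells occupied by the species.
#' @param aoe_cells integer vector of cells forming the candidate area.
#' @return list with `a`, `b`, `c`, `index`.
#' @examples
#' species_fit(1:10, 1:10)$index       # 1
#' species_fit(1:3, 1:10)$index        # (100 + 30) / 200
#' @export
species_fit <- function(species_cells, aoe_cells) {
  if (!length(aoe_cells)) stop("degenerate area: empty cell set")
  if (!length(species_cells)) stop("empty species distribution")
  inter <- length(intersect(species_cells, aoe_cells))
  a <- 100 * inter / length(unique(species_cells))
  b <- 100 * inter / length(unique(aoe_cells))
  list(a = a, b = b, c = 200, index = (a + b) / 200)
}

#' Fit report of all taxa against candidate areas of endemism
#'
#' Rasterizes each candidate polygon to the presence/absence grid (cell
#' centroid inside the polygon), computes the fit components for every
#' taxon, and reports per area the qualifying taxa — those with more than
#' `qualify_threshold` percent of their distribution inside the area —
#' their mean fit index, and the number of exclusive taxa (`a = 100`).
#' Mean indices are reported both per area and pooled over all qualifying
#' (taxon, area) pairs.
#'
#' @param pam a `pam` from [build_presence_matrix()].
#' @param aoes named list of candidate areas: polygons (two-column lon/lat
#'   matrices) or integer cell-index vectors.
#' @param qualify_threshold minimum `a` (exclusive) for a taxon to qualify;
#'   default 90, i.e. more than 90 percent of the distribution inside.
#' @return list of class `fit_report`: `per_aoe` (list of data.frames of
#'   qualifying taxa with `a`, `b`, `index`), `summary` (data.frame with
#'   `aoe`, `n_qualifying`, `mean_index`, `n_exclusive`), `pooled_mean`,
#'   `unassigned_taxa` (qualify for no area).
#' @export
aoe_fit_report <- function(pam, aoes, qualify_threshold = 90) {
  if (is.null(names(aoes)))
    names(aoes) <- paste0("aoe_", seq_along(aoes))
  species_cells <- lapply(seq_along(pam$taxa), function(k) pam$cells[pam$m[, k] == 1])
  names(species_cells) <- pam$taxa
  per_aoe <- list()
  summary_rows <- list()
  qualified_any <- character(0)
  for (nm in names(aoes)) {
    a_cells <- aoes[[nm]]
    if (is.matrix(a_cells) || is.data.frame(a_cells))
      a_cells <- rasterize_polygon(pam$grid, as.matrix(a_cells))
    if (!length(a_cells)) {
      warning("area '", nm, "' rasterizes to zero cells; skipped")
      next
    }
    comp <- lapply(species_cells, species_fit, aoe_cells = a_cells)
    tab <- data.frame(
      taxon_id = names(comp),
      a = vapply(comp, `[[`, numeric(1), "a"),
      b = vapply(comp, `[[`, numeric(1), "b"),
      index = vapply(comp, `[[`, numeric(1), "index"),
      stringsAsFactors = FALSE
    )
    rownames(tab) <- NULL
    qual <- tab[tab$a > qualify_threshold, , drop = FALSE]
    per_aoe[[nm]] <- qual
    qualified_any <- union(qualified_any, qual$taxon_id)
    summary_rows[[nm]] <- data.frame(
      aoe = nm, n_qualifying = nrow(qual),
      mean_index = if (nrow(qual)) mean(qual$index) else NA_real_,
      n_exclusive = sum(qual$a == 100),
      stringsAsFactors = FALSE
    )
  }
  all_qual <- do.call(rbind, per_aoe)
  out <- list(
    per_aoe = per_aoe,
    summary = {
      s <- do.call(rbind, summary_rows); rownames(s) <- NULL; s
    },
    pooled_mean = if (NROW(all_qual)) mean(all_qual$index) else NA_real_,
    unassigned_taxa = setdiff(pam$taxa, qualified_any),
    qualify_threshold = qualify_threshold
  )
  class(out) <- "fit_report"
  out
}

#' @export
print.fit_report <- function(x, ...) {
  print(x$summary)
  cat(sprintf("pooled mean index over qualifying pairs: %.3f (threshold a > %g)\n",
              x$pooled_mean, x$qualify_threshold))
  invisible(x)
}
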