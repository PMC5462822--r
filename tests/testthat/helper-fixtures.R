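# shared fixture builders (everything generated in code; no stored data)

square_poly <- function(x0, y0, w, h = w) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# small presence/absence object assembled directly from a binary matrix
pam_from_matrix <- function(m, grid = grid_spec(c(0, 0, ncol_cells(m), 1), 1),
                            record_counts = NULL) {
  cells <- seq_len(nrow(m))
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", cells)
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  out <- list(grid = grid, taxa = colnames(m), cells = cells,
              m = m,
              record_counts = stats::setNames(
                if (is.null(record_counts)) rep(10L, nrow(m)) else record_counts,
                rownames(m)),
              n_outside = 0L)
  class(out) <- "pam"
  out
}

ncol_cells <- function(m) max(nrow(m), 3)

random_pam <- function(n_cells, n_taxa, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_cells * n_taxa, 1, p), n_cells, n_taxa)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  rownames(m) <- paste0("cell_", seq_len(n_cells))
  colnames(m) <- paste0("sp", seq_len(n_taxa))
  pam_from_matrix(m, grid_spec(c(0, 0, n_cells, 1), 1))
}

write_occurrence_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
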