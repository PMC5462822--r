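#' Read point occurrence records from delimited text
#'
#' Reads a CSV or TSV table of occurrence records, validates coordinates and
#' taxon identifiers, and returns clean records together with a rejection
#' report.  Column names follow the Darwin Core spelling by default and can
#' be remapped.
#'
#' @param path path to a delimited text file.  Files ending in `.tsv` or
#'   `.txt` are read as tab-separated, anything else as comma-separated.
#' @param column_map named character vector mapping the roles `taxon`, `lon`,
#'   `lat` to column names in the file.
#' @param sep field separator; overrides the extension heuristic.
#' @return list with components
#'   \describe{
#'     \item{records}{data.frame with `taxon_id`, `lon`, `lat`, `source_row`}
#'     \item{rejected}{data.frame with `source_row`, `reason`}
#'   }
#' @export
read_occurrences <- function(path,
                             column_map = c(taxon = "taxon",
                                            lon = "decimalLongitude",
                                            lat = "decimalLatitude"),
                             sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", comment.char = ""),
    error = function(e) stop("failed to read '", path, "': ", conditionMessage(e))
  )
  need <- c("taxon", "lon", "lat")
  if (is.null(names(column_map)) || !all(need %in% names(column_map)))
    stop("'column_map' must name columns for taxon, lon and lat")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  validate_occurrences(
    taxon = raw[[column_map[["taxon"]]]],
    lon = raw[[column_map[["lon"]]]],
    lat = raw[[column_map[["lat"]]]]
  )
}

# shared validation for file input and in-memory tables
validate_occurrences <- function(taxon, lon, lat) {
  n <- length(taxon)
  lon_num <- suppressWarnings(as.numeric(lon))
  lat_num <- suppressWarnings(as.numeric(lat))
  reason <- rep(NA_character_, n)
  nonnum <- (is.na(lon_num) & !is_blank(lon)) | (is.na(lat_num) & !is_blank(lat))
  reason[nonnum] <- "non-numeric coordinate"
  miss <- is.na(reason) & (is_blank(lon) | is_blank(lat))
  reason[miss] <- "missing coordinate"
  oor <- is.na(reason) &
    (lon_num < -180 | lon_num > 180 | lat_num < -90 | lat_num > 90)
  reason[oor] <- "out of range"
  no_taxon <- is.na(reason) & is_blank(taxon)
  reason[no_taxon] <- "missing taxon"
  ok <- is.na(reason)
  list(
    records = data.frame(
      taxon_id = as.character(taxon[ok]),
      lon = lon_num[ok],
      lat = lat_num[ok],
      source_row = which(ok),
      stringsAsFactors = FALSE
    ),
    rejected = data.frame(
      source_row = which(!ok),
      reason = reason[!ok],
      stringsAsFactors = FALSE
    )
  )
}

is_blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

#' Build a gridded presence/absence matrix
#'
#' Assigns records to grid cells (half-open cell convention, see
#' [grid_spec()]) and collapses repeated records of a taxon within a cell to
#' a single presence.  Raw record counts per cell are preserved as a
#' sampling-effort signal.  Records outside the grid extent are dropped and
#' reported.
#'
#' @param records data.frame with `taxon_id`, `lon`, `lat` (as returned by
#'   [read_occurrences()] or [generate_scenario()]).
#' @param grid a [grid_spec()].
#' @return object of class `pam`: list with `grid`, `taxa` (sorted), `cells`
#'   (sorted indices of occupied cells), `m` (binary cell x taxon matrix),
#'   `record_counts` (per retained cell), `n_outside`.
#' @export
build_presence_matrix <- function(records, grid) {
  if (NROW(records) == 0L) stop("no data: empty record list")
  idx <- cell_index(grid, records$lon, records$lat)
  inside <- !is.na(idx)
  if (!any(inside)) stop("no data: all records fall outside the grid extent")
  idx <- idx[inside]
  taxa_all <- as.character(records$taxon_id[inside])
  cells <- sort(unique(idx))
  taxa <- sort(unique(taxa_all))
  m <- matrix(0L, nrow = length(cells), ncol = length(taxa),
              dimnames = list(paste0("cell_", cells), taxa))
  ci <- match(idx, cells)
  ti <- match(taxa_all, taxa)
  m[cbind(ci, ti)] <- 1L
  counts <- as.integer(tabulate(ci, nbins = length(cells)))
  out <- list(grid = grid, taxa = taxa, cells = cells, m = m,
              record_counts = stats::setNames(counts, rownames(m)),
              n_outside = sum(!inside))
  class(out) <- "pam"
  out
}

#' @export
print.pam <- function(x, ...) {
  cat(sprintf("presence/absence matrix: %d occupied cells x %d taxa (%d records, %d outside grid)\n",
              length(x$cells), length(x$taxa), sum(x$record_counts), x$n_outside))
  invisible(x)
}

#' Drop poorly sampled grid cells
#'
#' Removes occupied cells whose raw record count falls below `min_records`
#' (default 10, i.e. cells with fewer than ten records are excluded), then
#' drops taxa left without any presence.
#'
#' @param pam a `pam` from [build_presence_matrix()].
#' @param min_records minimum number of records for a cell to be kept.
#' @return a filtered `pam`; attribute `dropped_taxa` lists taxa removed
#'   because all their cells were filtered out.
#' @export
filter_cells_by_records <- function(pam, min_records = 10) {
  keep <- pam$record_counts >= min_records
  if (!any(keep)) stop("no cells survive filter (min_records = ", min_records, ")")
  m <- pam$m[keep, , drop = FALSE]
  keep_tax <- colSums(m) > 0
  dropped <- pam$taxa[!keep_tax]
  out <- list(grid = pam$grid, taxa = pam$taxa[keep_tax],
              cells = pam$cells[keep], m = m[, keep_tax, drop = FALSE],
              record_counts = pam$record_counts[keep],
              n_outside = pam$n_outside)
  class(out) <- "pam"
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Per-taxon range summaries
#'
#' For each taxon, the range centroid (unweighted mean of coordinates) and
#' the great-circle distance from that centroid to the farthest record.
#' This centroid-to-farthest-point distance is the range-size measure that
#' feeds the GIE range categories.
#'
#' @param records data.frame with `taxon_id`, `lon`, `lat`.
#' @return data.frame with `taxon_id`, `centroid_lon`, `centroid_lat`,
#'   `max_dist_km`, `n_records`.
#' @export
taxon_range_summary <- function(records) {
  if (NROW(records) == 0L) stop("no data")
  sp <- split(seq_len(nrow(records)), records$taxon_id)
  res <- lapply(names(sp), function(tx) {
    i <- sp[[tx]]
    clon <- mean(records$lon[i])
    clat <- mean(records$lat[i])
    d <- haversine_km(c(clon, clat), cbind(records$lon[i], records$lat[i]))
    data.frame(taxon_id = tx, centroid_lon = clon, centroid_lat = clat,
               max_dist_km = max(d), n_records = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
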