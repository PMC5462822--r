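#' endemap: quantitative areas-of-endemism analysis
#'
#' Analysis pipeline for testing whether candidate biogeographic units
#' (such as river-bounded interfluves) are supported by point occurrence
#' data: kernel-interpolated endemism surfaces, species-to-area fit,
#' composition-break detection, Monmonier barriers, parsimony analysis of
#' endemicity, and synthetic benchmarks with planted structure.
#'
#' @keywords internal
"_PACKAGE"

#' Export a presence/absence matrix as wide CSV
#'
#' One row per occupied cell with its id, centroid and record count,
#' followed by one binary column per taxon.
#'
#' @param pam a `pam`.
#' @param path output file.
#' @export
write_pam_csv <- function(pam, path) {
  ctr <- cell_centroid(pam$grid, pam$cells)
  out <- cbind(data.frame(cell = rownames(pam$m), lon = ctr$lon,
                          lat = ctr$lat,
                          n_records = as.integer(pam$record_counts)),
               as.data.frame(pam$m))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

geojson_geometry <- function(type, coords) list(type = type, coordinates = coords)

#' Write polygons or lines as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for the package's vector
#' outputs (areas of endemism, barriers, planted rivers).
#'
#' @param features named list; each element a list with `geometry` (a
#'   two-column lon/lat matrix), `type` (`"Polygon"` or `"LineString"`)
#'   and optional `properties` (named list).
#' @param path output file.
#' @export
write_geojson <- function(features, path) {
  fs <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    coords <- unname(as.matrix(f$geometry))
    geom <- if (identical(f$type, "Polygon")) {
      ring <- rbind(coords, coords[1, ])
      geojson_geometry("Polygon", list(lapply(seq_len(nrow(ring)),
                                              function(r) ring[r, ])))
    } else {
      geojson_geometry("LineString", lapply(seq_len(nrow(coords)),
                                            function(r) coords[r, ]))
    }
    props <- if (is.null(f$properties)) stats::setNames(list(), character(0)) else f$properties
    props$name <- if (!is.null(names(features))) names(features)[i] else i
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export areas of endemism as GeoJSON polygons
#'
#' @param aoes an `aoe_set` from [delineate_aoes()].
#' @param path output file.
#' @export
write_aoe_geojson <- function(aoes, path) {
  feats <- lapply(aoes, function(a)
    list(geometry = a$polygon, type = "Polygon",
         properties = list(id = a$id, peak_index = a$peak_index,
                           n_synendemics = a$n_synendemics,
                           taxa = paste(a$supporting_taxa, collapse = ";"))))
  names(feats) <- paste0("aoe_", vapply(aoes, `[[`, numeric(1), "id"))
  write_geojson(feats, path)
}

#' Export Monmonier barriers as GeoJSON line strings
#'
#' @param barriers a `barrier_set`.
#' @param path output file.
#' @export
write_barrier_geojson <- function(barriers, path) {
  feats <- lapply(barriers, function(b)
    list(geometry = b$path, type = "LineString",
         properties = list(rank = b$rank,
                           seed_dissimilarity = b$seed_dissimilarity,
                           total_strength = b$total_strength)))
  names(feats) <- paste0("barrier_", vapply(barriers, `[[`, numeric(1), "rank"))
  write_geojson(feats, path)
}
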