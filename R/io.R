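# Plain-text interchange: CSV, GeoJSON (written directly -- the structures
# involved are simple rectangles and polylines), Newick via ape.

fmt_coord <- function(x, digits = 6) round(as.numeric(x), digits)

#' Write grid-cell polygons as GeoJSON
#'
#' One Polygon feature per cell with any extra columns of `cells` attached
#' as properties.  Coordinates are written at fixed precision so repeated
#' runs are byte-identical.
#'
#' @param cells data frame with `cell_id`, `lon_min`, `lat_min`, `lon_max`,
#'   `lat_max` plus optional property columns.
#' @param path output file.
#' @param digits coordinate precision (default 6 decimals).
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path, digits = 6) {
  geom_cols <- c("lon_min", "lat_min", "lon_max", "lat_max", "ix", "iy")
  prop_cols <- setdiff(names(cells), geom_cols)
  features <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- fmt_coord(cells$lon_min[i], digits); x1 <- fmt_coord(cells$lon_max[i], digits)
    y0 <- fmt_coord(cells$lat_min[i], digits); y1 <- fmt_coord(cells$lat_max[i], digits)
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(cells[i, prop_cols, drop = FALSE]))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write biogeographic tracks as GeoJSON
#'
#' One MultiLineString feature per track, with the district label and total
#' length as properties.
#'
#' @param tracks list of [mst_track()] objects.
#' @param path output file.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_tracks_geojson <- function(tracks, path, digits = 6) {
  features <- lapply(tracks, function(tr) {
    segs <- lapply(seq_len(nrow(tr$edges)), function(e) {
      i <- tr$edges$from[e]; j <- tr$edges$to[e]
      list(c(fmt_coord(tr$points$lon[i], digits), fmt_coord(tr$points$lat[i], digits)),
           c(fmt_coord(tr$points$lon[j], digits), fmt_coord(tr$points$lat[j], digits)))
    })
    list(type = "Feature",
         geometry = list(type = "MultiLineString", coordinates = segs),
         properties = list(district = tr$district %||% NA,
                           total_length_km = round(tr$total_length_km, 3)))
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a study-region polygon from GeoJSON
#'
#' Extracts the outer ring of the first Polygon geometry found (a bare
#' geometry, a Feature or a FeatureCollection).
#'
#' @param path GeoJSON file.
#' @return Two-column matrix of `(lon, lat)` vertices.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (identical(gj$type, "FeatureCollection")) gj$features[[1]]$geometry
          else if (identical(gj$type, "Feature")) gj$geometry
          else gj
  if (!identical(geom$type, "Polygon"))
    stop("no Polygon geometry found in ", path)
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param dendrogram an `hclust`/[wpgma()] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "hclust"))
  h <- dendrogram
  class(h) <- "hclust"
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Read occurrence records from CSV
#'
#' @param path CSV with at least species and coordinate columns.
#' @param species_col,lon_col,lat_col column names.
#' @return Data frame with those columns (and any others) preserved.
#' @export
read_occurrences_csv <- function(path, species_col = "species",
                                 lon_col = "decimalLongitude",
                                 lat_col = "decimalLatitude") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in c(species_col, lon_col, lat_col))
    if (!cl %in% names(df)) stop("missing column '", cl, "' in ", path)
  df
}

#' Serialize / restore a cell table as plain CSV files
#'
#' `write_cell_table` writes `<prefix>_cells.csv` (geometry and counts),
#' `<prefix>_records.csv` (long cell/species records) and
#' `<prefix>_merge_log.csv`; `read_cell_table` rebuilds the object.
#'
#' @param ct a `"cell_table"`.
#' @param dir directory.
#' @param prefix file-name prefix (default `"grid"`).
#' @return The written file paths (invisibly) / the restored `"cell_table"`.
#' @export
write_cell_table <- function(ct, dir, prefix = "grid") {
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".csv"))
  write.csv(ct$cells, p("cells"), row.names = FALSE)
  write.csv(ct$occurrences, p("records"), row.names = FALSE)
  write.csv(ct$merge_log, p("merge_log"), row.names = FALSE)
  invisible(c(p("cells"), p("records"), p("merge_log")))
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(dir, prefix = "grid") {
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".csv"))
  cells <- read.csv(p("cells"), stringsAsFactors = FALSE)
  occurrences <- read.csv(p("records"), stringsAsFactors = FALSE)
  merge_log <- if (file.exists(p("merge_log")))
    read.csv(p("merge_log"), stringsAsFactors = FALSE) else empty_merge_log()
  cz <- if (nrow(cells)) cells$lon_max[1] - cells$lon_min[1] else 0.25
  structure(list(cells = cells, occurrences = occurrences,
                 grid = grid_spec(cell_size = cz),
                 merge_log = merge_log, dropped = NULL),
            class = "cell_table")
}
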