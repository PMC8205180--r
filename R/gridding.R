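#' Specify a regular geographic grid
#'
#' Cells are half-open squares `[edge, edge + cell_size)` in both axes,
#' indexed from a lower-left origin with 0-based integer indices
#' `floor((coord - origin) / cell_size)`.
#'
#' @param origin numeric length-2 `(lon, lat)` of the grid lower-left corner,
#'   or `NULL` to snap to the data extent when the grid is first used.
#' @param cell_size cell edge length in decimal degrees (default 0.25).
#' @return A list of class `"grid_spec"`.
#' @export
grid_spec <- function(origin = NULL, cell_size = 0.25) {
  stopifnot_scalar_number(cell_size, "cell_size", lower = .Machine$double.eps)
  if (!is.null(origin) && (length(origin) != 2L || !is.numeric(origin)))
    stop("'origin' must be NULL or numeric length 2 (lon, lat)")
  structure(list(origin = origin, cell_size = cell_size), class = "grid_spec")
}

#' Curate occurrence records
#'
#' Applies coordinate-based curation: records must carry parseable
#' coordinates within valid geographic bounds and, when a study-region
#' polygon is given, fall inside it (points on the boundary are retained;
#' closed containment).  Species names are whitespace-normalized.
#'
#' @param records data frame of raw occurrences.
#' @param region optional study-region polygon: a two-column matrix or data
#'   frame of `(lon, lat)` vertices.
#' @param species_col,lon_col,lat_col column names in `records`.
#' @return A list of class `"curated_records"` with `records` (the retained
#'   rows, with normalized `species`, numeric `lon`, `lat`) and `report`, a
#'   named integer vector of rejection counts by cause (`missing_coords`,
#'   `invalid_coords`, `out_of_region`) plus `retained`.
#' @export
curate_records <- function(records, region = NULL,
                           species_col = "species",
                           lon_col = "decimalLongitude",
                           lat_col = "decimalLatitude") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame")
  for (cl in c(species_col, lon_col, lat_col))
    if (!cl %in% names(records)) stop("missing column '", cl, "'")
  lon <- suppressWarnings(as.numeric(records[[lon_col]]))
  lat <- suppressWarnings(as.numeric(records[[lat_col]]))
  species <- gsub("\\s+", " ", trimws(as.character(records[[species_col]])))
  missing <- is.na(lon) | is.na(lat) | !nzchar(species)
  invalid <- !missing & (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  out_reg <- rep(FALSE, nrow(records))
  if (!is.null(region)) {
    ok <- !missing & !invalid
    out_reg[ok] <- !point_in_polygon(lon[ok], lat[ok], as.matrix(region))
  }
  keep <- !missing & !invalid & !out_reg
  kept <- data.frame(species = species[keep], lon = lon[keep], lat = lat[keep],
                     stringsAsFactors = FALSE)
  if ("source_id" %in% names(records)) kept$source_id <- records$source_id[keep]
  report <- c(retained = sum(keep), missing_coords = sum(missing),
              invalid_coords = sum(invalid), out_of_region = sum(out_reg))
  structure(list(records = kept, report = report), class = "curated_records")
}

#' @export
print.curated_records <- function(x, ...) {
  cat("Curated occurrence records:", x$report[["retained"]], "retained\n")
  rej <- x$report[setdiff(names(x$report), "retained")]
  rej <- rej[rej > 0]
  if (length(rej)) cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej),
                                            collapse = ", "), "\n")
  invisible(x)
}

cell_index <- function(coord, origin, cell_size) {
  # half-open [edge, edge + size); 1e-9 absorbs floating-point edge noise
  as.integer(floor((coord - origin) / cell_size + 1e-9))
}

#' Assign curated records to grid cells
#'
#' @param curated a [curate_records()] result (or a data frame with `species`,
#'   `lon`, `lat`).
#' @param grid a [grid_spec()].
#' @return An object of class `"cell_table"`: a list with `cells` (data frame
#'   of cell geometry and record counts), `occurrences` (long data frame
#'   `cell_id`, `species`, one row per record), `grid`, and an empty
#'   `merge_log`.
#' @export
assign_to_grid <- function(curated, grid = grid_spec()) {
  recs <- if (inherits(curated, "curated_records")) curated$records else curated
  stopifnot(is.data.frame(recs))
  if (!all(c("lon", "lat") %in% names(recs)) &&
      all(c("decimalLongitude", "decimalLatitude") %in% names(recs))) {
    recs$lon <- recs$decimalLongitude
    recs$lat <- recs$decimalLatitude
  }
  stopifnot(all(c("species", "lon", "lat") %in% names(recs)))
  if (nrow(recs) == 0L) stop("no records to grid")
  origin <- grid$origin
  if (is.null(origin)) {
    origin <- c(floor(min(recs$lon) / grid$cell_size) * grid$cell_size,
                floor(min(recs$lat) / grid$cell_size) * grid$cell_size)
    grid$origin <- origin
  }
  ix <- cell_index(recs$lon, origin[1], grid$cell_size)
  iy <- cell_index(recs$lat, origin[2], grid$cell_size)
  if (any(ix < 0L) || any(iy < 0L))
    stop("records fall below the grid origin; adjust grid_spec(origin=)")
  cell_id <- sprintf("c%03d_%03d", ix, iy)
  occurrences <- data.frame(cell_id = cell_id, species = recs$species,
                            stringsAsFactors = FALSE)
  u <- !duplicated(cell_id)
  cells <- data.frame(
    cell_id = cell_id[u], ix = ix[u], iy = iy[u],
    lon_min = origin[1] + ix[u] * grid$cell_size,
    lat_min = origin[2] + iy[u] * grid$cell_size,
    stringsAsFactors = FALSE
  )
  cells$lon_max <- cells$lon_min + grid$cell_size
  cells$lat_max <- cells$lat_min + grid$cell_size
  cnt <- table(cell_id)
  cells$n_records <- as.integer(cnt[cells$cell_id])
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, occurrences = occurrences, grid = grid,
                 merge_log = empty_merge_log(), dropped = NULL),
            class = "cell_table")
}

empty_merge_log <- function() {
  data.frame(from = character(0), to = character(0),
             n_records = integer(0), ring = integer(0),
             stringsAsFactors = FALSE)
}

#' Exclude poorly sampled cells, merging their records into neighbours
#'
#' Cells with fewer than `min_records` records are excluded from the retained
#' set; each excluded cell's records are transferred to exactly one retained
#' neighbour so that no information is lost.  The receiver is the retained
#' cell with the highest original record count among the queen-adjacent
#' neighbours (ties: lowest `cell_id`), searching outward ring by ring up to
#' `max_ring` Chebyshev rings.  Excluded cells are processed in ascending
#' record-count order against the original retained set, so the result does
#' not depend on transfer order and a cell can never become retained
#' mid-pass.
#'
#' @param ct a [assign_to_grid()] cell table.
#' @param min_records minimum records for a cell to be retained (default 5).
#' @param max_ring maximum Chebyshev search radius in cells (default 2).
#' @param orphans what to do with excluded cells that have no retained cell
#'   within `max_ring`: `"drop"` (default, with a warning; logged in
#'   `$dropped`) or `"error"`.
#' @return The filtered `"cell_table"`, with `merge_log` describing every
#'   transfer.  Total record count is conserved up to explicitly dropped
#'   orphans.
#' @export
filter_and_merge <- function(ct, min_records = 5, max_ring = 2,
                             orphans = c("drop", "error")) {
  stopifnot(inherits(ct, "cell_table"))
  orphans <- match.arg(orphans)
  cells <- ct$cells
  retained <- cells$n_records >= min_records
  if (all(retained)) return(ct)
  if (!any(retained)) {
    stop("no cell reaches min_records = ", min_records)
  }
  ret <- cells[retained, ]
  exc <- cells[!retained, ]
  exc <- exc[order(exc$n_records, exc$cell_id), ]
  occ <- ct$occurrences
  log <- empty_merge_log()
  dropped <- character(0)
  for (i in seq_len(nrow(exc))) {
    dx <- abs(ret$ix - exc$ix[i]); dy <- abs(ret$iy - exc$iy[i])
    ring <- pmax(dx, dy)
    receiver <- NA_character_
    for (r in seq_len(max_ring)) {
      cand <- ret[ring == r, ]
      if (nrow(cand)) {
        cand <- cand[order(-cand$n_records, cand$cell_id), ]
        receiver <- cand$cell_id[1]
        break
      }
    }
    if (is.na(receiver)) {
      if (orphans == "error")
        stop("excluded cell ", exc$cell_id[i], " has no retained neighbour within ",
             max_ring, " rings")
      dropped <- c(dropped, exc$cell_id[i])
      next
    }
    log <- rbind(log, data.frame(from = exc$cell_id[i], to = receiver,
                                 n_records = exc$n_records[i], ring = r,
                                 stringsAsFactors = FALSE))
  }
  if (length(dropped)) {
    warning(length(dropped), " excluded cell(s) had no retained neighbour within ",
            max_ring, " rings and were dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    occ <- occ[!occ$cell_id %in% dropped, ]
  }
  if (nrow(log)) {
    map <- stats::setNames(log$to, log$from)
    hit <- occ$cell_id %in% names(map)
    occ$cell_id[hit] <- unname(map[occ$cell_id[hit]])
  }
  new_cells <- ct$cells[retained, ]
  cnt <- table(occ$cell_id)
  new_cells$n_records <- as.integer(cnt[new_cells$cell_id])
  new_cells <- new_cells[order(new_cells$cell_id), ]
  rownames(new_cells) <- NULL
  structure(list(cells = new_cells, occurrences = occ, grid = ct$grid,
                 merge_log = rbind(ct$merge_log, log),
                 dropped = if (length(dropped)) dropped else NULL),
            class = "cell_table")
}

#' Cell-by-species incidence matrix
#'
#' @param ct a `"cell_table"`.
#' @return Integer 0/1 matrix; rows are sorted cell ids, columns sorted
#'   species names; an entry is 1 iff the species has at least one record in
#'   the cell.
#' @export
incidence_matrix <- function(ct) {
  stopifnot(inherits(ct, "cell_table"))
  occ <- ct$occurrences
  cell_ids <- sort(unique(ct$cells$cell_id))
  species <- sort(unique(occ$species))
  m <- matrix(0L, nrow = length(cell_ids), ncol = length(species),
              dimnames = list(cell_ids, species))
  m[cbind(match(occ$cell_id, cell_ids), match(occ$species, species))] <- 1L
  m
}

#' Per-cell species sets
#'
#' @param ct a `"cell_table"`.
#' @return Named list mapping each cell id to its sorted species vector.
#' @export
species_sets <- function(ct) {
  stopifnot(inherits(ct, "cell_table"))
  s <- lapply(split(ct$occurrences$species, ct$occurrences$cell_id),
              function(x) sort(unique(x)))
  s[sort(names(s))]
}

#' Grid occurrence records end to end
#'
#' Convenience wrapper: [curate_records()], [assign_to_grid()] and
#' [filter_and_merge()] in sequence.
#'
#' @inheritParams curate_records
#' @inheritParams assign_to_grid
#' @inheritParams filter_and_merge
#' @return A filtered `"cell_table"`; the curation report is attached as
#'   attribute `"curation"`.
#' @export
grid_occurrences <- function(records, grid = grid_spec(), region = NULL,
                             min_records = 5, max_ring = 2,
                             species_col = "species",
                             lon_col = "decimalLongitude",
                             lat_col = "decimalLatitude") {
  cur <- curate_records(records, region = region, species_col = species_col,
                        lon_col = lon_col, lat_col = lat_col)
  ct <- assign_to_grid(cur, grid)
  ct <- filter_and_merge(ct, min_records = min_records, max_ring = max_ring)
  attr(ct, "curation") <- cur$report
  ct
}

#' @export
print.cell_table <- function(x, ...) {
  cat("Cell table:", nrow(x$cells), "retained cells,",
      nrow(x$occurrences), "records,",
      length(unique(x$occurrences$species)), "species\n")
  if (nrow(x$merge_log))
    cat("  merged", nrow(x$merge_log), "under-sampled cell(s) into neighbours\n")
  if (!is.null(x$dropped))
    cat("  dropped", length(x$dropped), "orphan cell(s)\n")
  invisible(x)
}
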