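#' Fit environmental vectors onto an ordination
#'
#' Relative environmental turnover: each environmental variable is regressed
#' on the ordination axes by least squares; its direction cosines give the
#' fitted vector, the squared multiple correlation `r2` its strength, and
#' significance comes from permuting the variable's values across cells
#' (`p = (#{r2_perm >= r2_obs} + 1) / (P + 1)`).
#'
#' @param ordination an [nmds()] fit or a score matrix (cells x axes, row
#'   names = cell ids).
#' @param env environmental table (`cell_id` + numeric columns), typically
#'   standardized; must cover every ordinated cell.
#' @param permutations permutations per variable (default 999).
#' @param seed optional integer seed.
#' @return Object of class `"env_vectors"`: `vectors` (data frame with one
#'   row per variable: unit direction cosines per axis, `r2`, `p_value`),
#'   `arrows` (directions scaled by `sqrt(r2)`, for plotting), and
#'   `permutations`.
#' @export
env_vectors <- function(ordination, env, permutations = 999, seed = NULL) {
  sc <- if (inherits(ordination, "nmds")) ordination$scores else as.matrix(ordination)
  ev <- env_values(env)
  if (!all(rownames(sc) %in% ev$id))
    stop("env table does not cover all ordinated cells")
  m <- ev$m[match(rownames(sc), ev$id), , drop = FALSE]
  Sc <- scale(sc, center = TRUE, scale = FALSE)
  qs <- qr(Sc)
  Qs <- qr.Q(qs)
  k <- ncol(sc)
  res <- with_seed(seed, {
    lapply(colnames(m), function(vn) {
      v <- m[, vn]
      vc <- v - mean(v)
      ss_tot <- sum(vc^2)
      if (ss_tot == 0) stop("constant variable: ", vn)
      r2 <- sum((t(Qs) %*% vc)^2) / ss_tot
      b <- qr.coef(qs, vc)
      dir <- if (sqrt(sum(b^2)) > 0) b / sqrt(sum(b^2)) else b
      r2_perm <- vapply(seq_len(permutations), function(i) {
        vp <- vc[sample.int(length(vc))]
        sum((t(Qs) %*% vp)^2) / ss_tot
      }, numeric(1))
      p <- (sum(r2_perm >= r2 - 1e-12) + 1) / (permutations + 1)
      c(dir, r2 = r2, p_value = p)
    })
  })
  tab <- as.data.frame(do.call(rbind, res))
  names(tab)[seq_len(k)] <- colnames(sc)
  tab <- data.frame(variable = colnames(m), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  arrows <- as.matrix(tab[, colnames(sc), drop = FALSE]) * sqrt(tab$r2)
  rownames(arrows) <- tab$variable
  structure(list(vectors = tab, arrows = arrows, permutations = permutations),
            class = "env_vectors")
}

#' @export
print.env_vectors <- function(x, digits = 4, ...) {
  cat("Environmental vectors fitted onto the ordination (",
      x$permutations, " permutations)\n", sep = "")
  tab <- x$vectors
  tab$sig <- ifelse(tab$p_value <= 0.001, "***",
                    ifelse(tab$p_value <= 0.01, "**",
                           ifelse(tab$p_value <= 0.05, "*", "")))
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.env_vectors <- function(x, scale = 1, col = "firebrick", ...) {
  arrows(0, 0, scale * x$arrows[, 1], scale * x$arrows[, 2],
         length = 0.08, col = col)
  text(1.1 * scale * x$arrows[, 1], 1.1 * scale * x$arrows[, 2],
       rownames(x$arrows), col = col, cex = 0.8)
  invisible(x)
}

#' District-exclusive (restricted) species
#'
#' A species is exclusive to a district when every cell it occurs in belongs
#' to that district; species recorded in more than one district belong to no
#' list.
#'
#' @param ct a `"cell_table"` (or a named list of per-cell species sets).
#' @param assignment a [consolidate_districts()] region assignment (or a
#'   named cell -> district vector).
#' @return Named list of class `"exclusive_species"`, one sorted species
#'   vector per district.
#' @export
exclusive_species <- function(ct, assignment) {
  sets <- if (inherits(ct, "cell_table")) species_sets(ct) else ct
  dd <- if (is.data.frame(assignment))
    stats::setNames(assignment$district, assignment$cell_id) else assignment
  if (!all(names(sets) %in% names(dd)))
    stop("assignment does not cover all cells")
  long <- data.frame(
    species = unlist(sets, use.names = FALSE),
    district = rep(unname(dd[names(sets)]), lengths(sets)),
    stringsAsFactors = FALSE
  )
  by_sp <- tapply(long$district, long$species,
                  function(d) if (length(unique(d)) == 1L) d[1] else NA_character_)
  out <- lapply(sort(unique(unname(dd))), function(D) {
    sort(names(by_sp)[!is.na(by_sp) & by_sp == D])
  })
  names(out) <- sort(unique(unname(dd)))
  structure(out, class = "exclusive_species")
}

#' @export
print.exclusive_species <- function(x, ...) {
  cat("District-exclusive species:\n")
  for (d in names(x)) cat(sprintf("  %s: %d species\n", d, length(x[[d]])))
  invisible(x)
}

haversine_km <- function(p) {
  # pairwise great-circle distances (km) on a spherical Earth, R = 6371 km
  geosphere::distm(p, fun = geosphere::distHaversine) / 1000
}

#' Minimum-spanning-tree biogeographic track
#'
#' Links a set of collecting points by the spanning tree of minimal total
#' great-circle (haversine) length.  Duplicate coordinates are collapsed
#' first; points are ordered lexicographically and Prim's algorithm breaks
#' equal-weight ties towards the lowest point indices, so the tree is
#' deterministic.
#'
#' @param points data frame or matrix with longitude and latitude columns
#'   (`lon`/`lat` or `decimalLongitude`/`decimalLatitude`); at least two
#'   distinct points.
#' @param district optional district label stored on the track.
#' @return Object of class `"track"`: `points` (deduplicated, ordered),
#'   `edges` (data frame `from`, `to`, `length_km`), `total_length_km`,
#'   `district`.
#' @export
mst_track <- function(points, district = NULL) {
  p <- as.data.frame(points)
  lon <- p$lon %||% p$decimalLongitude
  lat <- p$lat %||% p$decimalLatitude
  if (is.null(lon) || is.null(lat)) stop("need lon/lat columns")
  xy <- unique(data.frame(lon = lon, lat = lat))
  xy <- xy[order(xy$lon, xy$lat), ]
  rownames(xy) <- NULL
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 distinct points for a track")
  D <- haversine_km(as.matrix(xy))
  # Prim's algorithm; ties resolved towards the lowest indices
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_d <- D[1, ]; best_from <- rep(1L, n)
  edges <- data.frame(from = integer(n - 1L), to = integer(n - 1L),
                      length_km = numeric(n - 1L))
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best_d[cand])]
    edges[e, ] <- list(best_from[nxt], nxt, best_d[nxt])
    in_tree[nxt] <- TRUE
    upd <- !in_tree & D[nxt, ] < best_d
    best_d[upd] <- D[nxt, upd]
    best_from[upd] <- nxt
  }
  structure(list(points = xy, edges = edges,
                 total_length_km = sum(edges$length_km),
                 district = district),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat("Biogeographic track",
      if (!is.null(x$district)) paste0("(district ", x$district, ")"), ":",
      nrow(x$points), "points,", nrow(x$edges), "edges, total",
      sprintf("%.1f km\n", x$total_length_km))
  invisible(x)
}

#' Minimum-spanning-tree tracks of the exclusive species of each district
#'
#' @param records occurrence records (with species and lon/lat columns).
#' @param exclusive an [exclusive_species()] result.
#' @return Named list of [mst_track()] objects, one per district with at
#'   least two distinct exclusive-species collecting points; districts with
#'   fewer points are skipped with a message.
#' @export
biogeographic_tracks <- function(records, exclusive) {
  p <- as.data.frame(records)
  lon <- p$lon %||% p$decimalLongitude
  lat <- p$lat %||% p$decimalLatitude
  out <- list()
  for (d in names(exclusive)) {
    sel <- p$species %in% exclusive[[d]]
    pts <- unique(data.frame(lon = lon[sel], lat = lat[sel]))
    if (nrow(pts) < 2L) {
      message("district ", d, ": fewer than 2 exclusive-species points; no track")
      next
    }
    out[[d]] <- mst_track(pts, district = d)
  }
  out
}
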