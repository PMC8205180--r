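#' Specify a synthetic two-district landscape
#'
#' Describes the geographic extent, grid resolution and elevation model of a
#' synthetic landscape split into two contiguous districts by an elevation
#' threshold.  District `"A"` collects the cells at or above the threshold
#' (the highland district), `"B"` the cells below it.
#'
#' The elevation surface is a linear west-to-east ramp plus an optional
#' smoothed Gaussian random field.  The ramp guarantees that the two districts
#' are spatially contiguous; the random field roughens the boundary.
#'
#' @param extent numeric length-4, `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees.
#' @param cell_size grid resolution in decimal degrees (default 0.25).
#' @param ramp numeric length-2, elevation in metres at the west and east edge
#'   of the extent; cell elevation interpolates linearly in longitude.
#' @param noise_sd standard deviation (m) of the Gaussian random field added
#'   to the ramp; 0 disables it.
#' @param noise_smooth spatial-autocorrelation length of the field, in cells.
#' @param threshold elevation (m) separating district A (>= threshold) from
#'   district B (default 750).
#' @return A list of class `"landscape_spec"`.
#' @seealso [generate_landscape()]
#' @export
landscape_spec <- function(extent = c(-103, -100, 16, 19),
                           cell_size = 0.25,
                           ramp = c(0, 1500),
                           noise_sd = 120,
                           noise_smooth = 2,
                           threshold = 750) {
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("'extent' must be c(lon_min, lon_max, lat_min, lat_max) with positive spans")
  stopifnot_scalar_number(cell_size, "cell_size", lower = .Machine$double.eps)
  if (length(ramp) != 2L || !is.numeric(ramp)) stop("'ramp' must be length-2 numeric")
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(threshold, "threshold")
  structure(list(extent = as.numeric(extent), cell_size = cell_size,
                 ramp = as.numeric(ramp), noise_sd = noise_sd,
                 noise_smooth = noise_smooth, threshold = threshold),
            class = "landscape_spec")
}

# Smoothed standard-normal field on an nx x ny grid; `smooth` is the Gaussian
# kernel sd in cells.  Rescaled to unit marginal sd (smoothing shrinks it).
smooth_gaussian_field <- function(nx, ny, smooth = 0) {
  z <- matrix(rnorm(nx * ny), nrow = nx, ncol = ny)
  if (smooth > 0) {
    r <- max(1L, ceiling(2 * smooth))
    w <- exp(-(seq(-r, r))^2 / (2 * smooth^2))
    w <- w / sum(w)
    pad <- function(m, k) m[pmin(pmax(seq_len(nrow(m) + 2 * k) - k, 1), nrow(m)), , drop = FALSE]
    # separable convolution with edge replication
    zc <- pad(z, r)
    z1 <- matrix(0, nx, ny)
    for (i in seq_along(w)) z1 <- z1 + w[i] * zc[i:(i + nx - 1L), , drop = FALSE]
    zc <- t(pad(t(z1), r))
    z2 <- matrix(0, nx, ny)
    for (i in seq_along(w)) z2 <- z2 + w[i] * zc[, i:(i + ny - 1L), drop = FALSE]
    s <- stats::sd(as.vector(z2))
    z <- if (s > 0) z2 / s else z2
  }
  z
}

#' Generate a labelled synthetic landscape
#'
#' Realizes a [landscape_spec()] into a grid of cells carrying an elevation
#' and a true district label: `"A"` where elevation >= threshold, `"B"`
#' elsewhere.  The same seed always yields an identical landscape.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed for the elevation noise field.
#' @param allow_single_district keep a landscape whose cells all fall in one
#'   district instead of raising an error (default `FALSE`; the downstream
#'   analysis needs both districts).
#' @return An object of class `"landscape"`: a list with `cells` (data frame
#'   with `cell_id`, integer indices `ix`/`iy`, centre `lon`/`lat`,
#'   `elevation` and `district`) and the originating `spec`.
#' @examples
#' ls <- generate_landscape(landscape_spec(), seed = 1)
#' table(ls$cells$district)
#' @export
generate_landscape <- function(spec = landscape_spec(), seed = 1,
                               allow_single_district = FALSE) {
  stopifnot(inherits(spec, "landscape_spec"))
  ext <- spec$extent
  nx <- max(1L, floor(round((ext[2] - ext[1]) / spec$cell_size, 9)))
  ny <- max(1L, floor(round((ext[4] - ext[3]) / spec$cell_size, 9)))
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  lon <- ext[1] + (ix + 0.5) * spec$cell_size
  lat <- ext[3] + (iy + 0.5) * spec$cell_size
  # ramp interpolates cell centres: west-most centre -> ramp[1], east-most -> ramp[2]
  frac <- if (nx > 1L) (lon - min(lon)) / (max(lon) - min(lon)) else rep(0.5, length(lon))
  elev_ramp <- spec$ramp[1] + frac * (spec$ramp[2] - spec$ramp[1])
  noise <- if (spec$noise_sd > 0) {
    f <- with_seed(seed, smooth_gaussian_field(nx, ny, spec$noise_smooth))
    spec$noise_sd * f[cbind(ix + 1L, iy + 1L)]
  } else 0
  elevation <- elev_ramp + noise
  district <- ifelse(elevation >= spec$threshold, "A", "B")
  if (length(unique(district)) < 2L && !allow_single_district) {
    stop("single-district landscape: elevation threshold ", spec$threshold,
         " m leaves every cell in district ", district[1])
  }
  cells <- data.frame(
    cell_id = sprintf("c%03d_%03d", ix, iy),
    ix = ix, iy = iy, lon = lon, lat = lat,
    elevation = elevation, district = district,
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, spec = spec), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  tab <- table(x$cells$district)
  cat("Synthetic landscape:", nrow(x$cells), "cells of", x$spec$cell_size,
      "deg\n  districts (threshold", x$spec$threshold, "m):",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Specify a synthetic species community
#'
#' Three species pools are planted on the landscape: species exclusive to
#' district A, species exclusive to district B, and shared species that may
#' occur anywhere.  Sampling effort per cell is Poisson (or negative binomial
#' when overdispersed) and each record draws a species uniformly from the
#' cell's pool, thinned by a detection probability.
#'
#' Defaults emulate a well-collected regional herbarium database: about a
#' hundred species, around sixty records per cell, and a strongly asymmetric
#' exclusive pool (the highland district much richer in restricted species).
#'
#' @param n_exclusive_a,n_exclusive_b,n_shared pool sizes (counts >= 0; at
#'   least two species in total).
#' @param detection_prob probability that a sampled individual is recorded.
#' @param effort_mean mean number of records per cell.
#' @param effort_overdispersion non-negative; 0 gives Poisson effort,
#'   otherwise negative-binomial with this dispersion (variance
#'   mu + overdispersion * mu^2).
#' @param seed default seed used by [generate_occurrences()].
#' @return A list of class `"community_spec"`.
#' @export
community_spec <- function(n_exclusive_a = 50, n_exclusive_b = 10,
                           n_shared = 40, detection_prob = 1,
                           effort_mean = 60, effort_overdispersion = 0,
                           seed = 1) {
  counts <- c(n_exclusive_a, n_exclusive_b, n_shared)
  if (any(counts < 0) || sum(counts) < 2)
    stop("species counts must be >= 0 and sum to at least 2")
  if (!(detection_prob > 0 && detection_prob <= 1))
    stop("'detection_prob' must be in (0, 1]")
  stopifnot_scalar_number(effort_mean, "effort_mean", lower = 0)
  stopifnot_scalar_number(effort_overdispersion, "effort_overdispersion", lower = 0)
  structure(list(n_exclusive_a = n_exclusive_a, n_exclusive_b = n_exclusive_b,
                 n_shared = n_shared, detection_prob = detection_prob,
                 effort_mean = effort_mean,
                 effort_overdispersion = effort_overdispersion, seed = seed),
            class = "community_spec")
}

#' Generate synthetic occurrence records
#'
#' Places occurrence records on a labelled landscape according to a
#' [community_spec()].  Exclusive-A species can only be recorded in A cells
#' (and B in B cells); shared species occur in every cell's pool.  Records
#' are positioned uniformly at random within their cell.
#'
#' @param landscape a [generate_landscape()] result.
#' @param community a [community_spec()].
#' @param seed integer seed; defaults to `community$seed`.
#' @return Data frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `source_id`, plus a hidden `cell_id` column recording
#'   the generating cell (useful for truth checks).
#' @export
generate_occurrences <- function(landscape, community = community_spec(),
                                 seed = community$seed) {
  stopifnot(inherits(landscape, "landscape"), inherits(community, "community_spec"))
  cells <- landscape$cells
  cz <- landscape$spec$cell_size
  pools <- list(
    A = c(species_names("exclA", community$n_exclusive_a),
          species_names("shared", community$n_shared)),
    B = c(species_names("exclB", community$n_exclusive_b),
          species_names("shared", community$n_shared))
  )
  with_seed(seed, {
    n_rec <- if (community$effort_overdispersion > 0) {
      rnbinom(nrow(cells), size = 1 / community$effort_overdispersion,
              mu = community$effort_mean)
    } else {
      rpois(nrow(cells), community$effort_mean)
    }
    out <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      k <- n_rec[i]
      if (k == 0L) next
      pool <- pools[[cells$district[i]]]
      if (length(pool) == 0L) next
      sp <- sample(pool, k, replace = TRUE)
      keep <- runif(k) <= community$detection_prob
      if (!any(keep)) next
      sp <- sp[keep]
      out[[i]] <- data.frame(
        species = sp,
        decimalLongitude = cells$lon[i] + runif(length(sp), -0.5, 0.5) * cz,
        decimalLatitude = cells$lat[i] + runif(length(sp), -0.5, 0.5) * cz,
        cell_id = cells$cell_id[i],
        stringsAsFactors = FALSE
      )
    }
    recs <- do.call(rbind, out)
    if (is.null(recs) || nrow(recs) == 0L)
      stop("zero occurrence records generated; increase effort_mean or detection_prob")
    recs$source_id <- sprintf("syn-%06d", seq_len(nrow(recs)))
    rownames(recs) <- NULL
    recs[, c("species", "decimalLongitude", "decimalLatitude", "source_id", "cell_id")]
  })
}

species_names <- function(prefix, n) {
  if (n <= 0) return(character(0))
  sprintf("%s_%03d", prefix, seq_len(n))
}

#' Specify synthetic environmental layers
#'
#' Each layer is drawn per cell from a district-conditional Gaussian:
#' `Normal(mean of the cell's district, sd of that district)`, optionally
#' spatially smoothed.  `sd` may be a single value or `c(sd_A, sd_B)`.
#'
#' @param name variable name.
#' @param mean_a,mean_b district means.
#' @param sd standard deviation, length 1 or 2 (district A, B).
#' @param autocorr spatial-autocorrelation length in cells (0 = independent).
#' @return A list of class `"env_layer"`.
#' @export
env_layer <- function(name, mean_a, mean_b, sd, autocorr = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (any(sd < 0)) stop("'sd' must be >= 0")
  if (!length(sd) %in% c(1L, 2L)) stop("'sd' must have length 1 or 2")
  structure(list(name = name, mean_a = mean_a, mean_b = mean_b,
                 sd = rep_len(as.numeric(sd), 2L), autocorr = autocorr),
            class = "env_layer")
}

#' Default environmental layers of the synthetic study
#'
#' Soil calcium and magnesium, precipitation seasonality and driest-quarter
#' precipitation, with district contrasts typical of a seasonally dry
#' tropical forest split across an elevation gradient: the highland district
#' has markedly higher soil Ca, slightly lower Mg, lower precipitation
#' seasonality and wetter dry seasons.
#'
#' @return List of [env_layer()] objects.
#' @export
default_env_layers <- function() {
  list(
    env_layer("soil_ca", mean_a = 0.93, mean_b = 0.40, sd = c(0.49, 0.16)),
    env_layer("soil_mg", mean_a = 0.29, mean_b = 0.32, sd = c(0.08, 0.07)),
    env_layer("prec_seasonality", mean_a = 78, mean_b = 88, sd = 6),
    env_layer("prec_driest_quarter", mean_a = 40, mean_b = 25, sd = 8)
  )
}

#' Generate a per-cell environmental table
#'
#' @param landscape a labelled [generate_landscape()] result.
#' @param layers list of [env_layer()] specifications.
#' @param seed integer seed.
#' @return Data frame with `cell_id` and one column per layer, rows in
#'   `cell_id` order.
#' @export
generate_env_table <- function(landscape, layers = default_env_layers(),
                               seed = 1) {
  stopifnot(inherits(landscape, "landscape"))
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  cells <- landscape$cells
  nx <- max(cells$ix) + 1L; ny <- max(cells$iy) + 1L
  is_a <- cells$district == "A"
  out <- data.frame(cell_id = cells$cell_id, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (l in layers) {
      z <- if (l$autocorr > 0) {
        f <- smooth_gaussian_field(nx, ny, l$autocorr)
        f[cbind(cells$ix + 1L, cells$iy + 1L)]
      } else rnorm(nrow(cells))
      sd_cell <- ifelse(is_a, l$sd[1], l$sd[2])
      out[[l$name]] <- ifelse(is_a, l$mean_a, l$mean_b) + sd_cell * z
    }
  })
  out
}
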