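#' Default pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()].  All analysis
#' defaults mirror the package's standard settings: 0.25-degree cells,
#' exclusion of cells with fewer than five records (merged into neighbours),
#' eight compositional groups consolidated into two districts, and 999
#' permutations for every permutation test.
#'
#' @param output_dir directory for all stage outputs.
#' @param occurrences,env,region optional input file paths (occurrence CSV,
#'   per-cell environment CSV, region-polygon GeoJSON).  When `occurrences`
#'   is `NULL` the synthetic generator supplies the data.
#' @param preset synthetic preset: `"scaled"` (about 100 species on a 12 x 12
#'   landscape; runs in seconds) or `"full_scale"` (571 species, 13 x 12
#'   landscape).
#' @param seed master integer seed; per-stage seeds are derived from it and
#'   recorded in the manifest.
#' @param ... named overrides merged into the defaults, e.g.
#'   `grid = list(min_records = 1)`.
#' @return A nested list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(output_dir = tempfile("phytodistricts_"),
                            occurrences = NULL, env = NULL, region = NULL,
                            preset = c("scaled", "full_scale"),
                            seed = 1, ...) {
  preset <- match.arg(preset)
  community <- if (preset == "full_scale") {
    community_spec(n_exclusive_a = 292, n_exclusive_b = 32, n_shared = 247,
                   effort_mean = 60, seed = seed)
  } else {
    community_spec(seed = seed)
  }
  landscape <- if (preset == "full_scale") {
    landscape_spec(extent = c(-103.25, -100, 16, 19))
  } else {
    landscape_spec()
  }
  cfg <- list(
    paths = list(occurrences = occurrences, env = env, region = region,
                 output_dir = output_dir),
    grid = list(origin = NULL, cell_size = 0.25, min_records = 5,
                max_ring = 2),
    clustering = list(k_groups = 8, k_final = 2),
    nmds = list(k = 2, restarts = 20, max_iter = 500, tol = 1e-7),
    rda = list(collinearity_threshold = 0.8, alpha = 0.05,
               permutations = 999),
    mrpp = list(permutations = 999),
    envfit = list(permutations = 999),
    synthetic = list(landscape = landscape, community = community,
                     layers = default_env_layers()),
    seed = seed
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[intersect(names(y), c("output_dir", "seed", "preset"))],
    y[["paths"]][intersect(names(y[["paths"]]), c("occurrences", "env", "region"))],
    y[setdiff(names(y), c("output_dir", "seed", "preset", "paths"))]
  ))
}

stage_seed <- function(cfg, k) (cfg$seed %||% 1) %% 20000000 * 100 + k

#' Write the synthetic dataset to disk
#'
#' Realizes the configuration's synthetic landscape and writes four files to
#' the output directory: `occurrences.csv` (species, decimalLongitude,
#' decimalLatitude, source_id), `env.csv` (cell_id + variables),
#' `truth.csv` (cell_id, true_district, elevation) and `cells.geojson`
#' (cell polygons).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the generated `landscape`, `occurrences`,
#'   `env` and the file `paths`.
#' @export
simulate_dataset <- function(config = pipeline_config()) {
  dir.create(config$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- config$paths$output_dir
  ls <- generate_landscape(config$synthetic$landscape,
                           seed = stage_seed(config, 1))
  occ <- generate_occurrences(ls, config$synthetic$community,
                              seed = stage_seed(config, 2))
  env <- generate_env_table(ls, config$synthetic$layers,
                            seed = stage_seed(config, 3))
  paths <- list(
    occurrences = file.path(out, "occurrences.csv"),
    env = file.path(out, "env.csv"),
    truth = file.path(out, "truth.csv"),
    cells = file.path(out, "cells.geojson")
  )
  write.csv(occ[, c("species", "decimalLongitude", "decimalLatitude", "source_id")],
            paths$occurrences, row.names = FALSE)
  write.csv(env, paths$env, row.names = FALSE)
  truth <- ls$cells[, c("cell_id", "district", "elevation")]
  names(truth)[2] <- "true_district"
  write.csv(truth, paths$truth, row.names = FALSE)
  cz <- ls$spec$cell_size
  cells_poly <- data.frame(cell_id = ls$cells$cell_id,
                           lon_min = ls$cells$lon - cz / 2,
                           lat_min = ls$cells$lat - cz / 2,
                           lon_max = ls$cells$lon + cz / 2,
                           lat_max = ls$cells$lat + cz / 2,
                           district = ls$cells$district)
  write_cells_geojson(cells_poly, paths$cells)
  invisible(list(landscape = ls, occurrences = occ, env = env, paths = paths))
}

run_stage_safely <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full regionalization pipeline
#'
#' Executes, in order: data acquisition (input CSVs or the synthetic
#' generator), gridding and cell filtering, beta-Simpson turnover, WPGMA
#' clustering with district consolidation, MRPP, NMDS, environmental-driver
#' selection (pruning, standardization, permutation forward selection),
#' environmental vector fitting, and exclusive-species MST tracks.  Every
#' intermediate artifact is written to the output directory and listed in a
#' reproducibility manifest (`manifest.json`) together with the derived
#' per-stage seeds and a hash of the configuration.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `"pipeline_result"` with the in-memory results of
#'   every stage plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  log <- list()

  # -- data
  synthetic <- is.null(config$paths$occurrences)
  dat <- run_stage_safely("data", {
    if (synthetic) {
      sim <- simulate_dataset(config)
      list(occ = sim$occurrences, env_path = sim$paths$env,
           files = unlist(sim$paths))
    } else {
      list(occ = read_occurrences_csv(config$paths$occurrences),
           env_path = config$paths$env,
           files = config$paths$occurrences)
    }
  })
  outputs$data <- unname(dat$files)
  log$n_records_raw <- nrow(dat$occ)

  # -- gridding
  region <- if (!is.null(config$paths$region))
    read_region_geojson(config$paths$region) else NULL
  ct <- run_stage_safely("gridding", {
    grid <- grid_spec(origin = config$grid$origin,
                      cell_size = config$grid$cell_size)
    grid_occurrences(dat$occ, grid = grid, region = region,
                     min_records = config$grid$min_records,
                     max_ring = config$grid$max_ring)
  })
  write_cell_table(ct, out)
  write_cells_geojson(ct$cells, file.path(out, "grid_cells.geojson"))
  outputs$gridding <- file.path(out, c("grid_cells.csv", "grid_records.csv",
                                       "grid_merge_log.csv", "grid_cells.geojson"))
  log$n_records_gridded <- nrow(ct$occurrences)
  log$n_cells_retained <- nrow(ct$cells)
  log$n_cells_merged <- nrow(ct$merge_log)

  # -- turnover
  d <- run_stage_safely("turnover", turnover_matrix(incidence_matrix(ct)))
  write_dist_csv(d, file.path(out, "turnover.csv"))
  outputs$turnover <- file.path(out, "turnover.csv")

  # -- clustering + consolidation
  reg <- run_stage_safely("clustering", {
    regionalize(d, k_groups = config$clustering$k_groups,
                k_final = config$clustering$k_final,
                permutations = config$mrpp$permutations,
                seed = stage_seed(config, 4))
  })
  reg$cells <- ct$cells
  write_newick(reg$dendrogram, file.path(out, "dendrogram.nwk"))
  write.csv(reg$assignment, file.path(out, "districts.csv"), row.names = FALSE)
  write_cells_geojson(merge(ct$cells, reg$assignment, by = "cell_id"),
                      file.path(out, "districts.geojson"))
  outputs$clustering <- file.path(out, c("dendrogram.nwk", "districts.csv",
                                         "districts.geojson"))
  log$district_sizes <- as.list(table(reg$assignment$district))

  # -- mrpp (fitted within regionalize; exported here)
  run_stage_safely("mrpp", {
    m <- reg$mrpp
    jsonlite::write_json(list(observed_delta = m$observed_delta,
                              group_stats = m$group_stats,
                              p_value = m$p_value, A = m$A,
                              permutations = m$permutations),
                         file.path(out, "mrpp.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  outputs$mrpp <- file.path(out, "mrpp.json")

  # -- nmds
  ord <- run_stage_safely("nmds", {
    nmds(d, k = config$nmds$k, restarts = config$nmds$restarts,
         max_iter = config$nmds$max_iter, tol = config$nmds$tol,
         seed = stage_seed(config, 5))
  })
  am <- axis_maps(ord, reg$assignment)
  sc_df <- data.frame(cell_id = rownames(am$scores), am$scores)
  write.csv(sc_df, file.path(out, "nmds_scores.csv"), row.names = FALSE)
  jsonlite::write_json(list(stress = ord$stress,
                            stress_quality = ord$stress_quality,
                            best_start = ord$best_start,
                            converged = ord$converged),
                       file.path(out, "nmds.json"), auto_unbox = TRUE, digits = NA)
  write_cells_geojson(merge(ct$cells, sc_df, by = "cell_id"),
                      file.path(out, "nmds_axes.geojson"))
  outputs$nmds <- file.path(out, c("nmds_scores.csv", "nmds.json",
                                   "nmds_axes.geojson"))
  log$nmds_stress <- ord$stress

  # -- environment: prune, standardize, forward-select RDA
  envsel <- if (is.null(dat$env_path)) NULL else run_stage_safely("environment", {
    env <- read.csv(dat$env_path, stringsAsFactors = FALSE)
    env <- env[env$cell_id %in% ct$cells$cell_id, ]
    pr <- prune_collinear(env, threshold = config$rda$collinearity_threshold)
    envz <- standardize_env(pr$env)
    inc <- incidence_matrix(ct)
    Yz <- scale(inc)          # z-scored incidence response
    Yz <- Yz[, !is.na(colSums(Yz)), drop = FALSE]
    fs <- forward_select(Yz, envz, permutations = config$rda$permutations,
                         alpha = config$rda$alpha,
                         seed = stage_seed(config, 6))
    list(pruning = pr, env = envz, selection = fs)
  })
  fit <- NULL
  if (!is.null(envsel)) {
    write.csv(envsel$pruning$dropped, file.path(out, "env_pruning.csv"),
              row.names = FALSE)
    write.csv(envsel$selection$steps, file.path(out, "rda_steps.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(selected = envsel$selection$selected,
                              proportion_explained = envsel$selection$proportion_explained,
                              alpha = envsel$selection$alpha,
                              permutations = envsel$selection$permutations),
                         file.path(out, "rda.json"), auto_unbox = TRUE, digits = NA)
    outputs$environment <- file.path(out, c("env_pruning.csv", "rda_steps.csv",
                                            "rda.json"))
    log$env_variables_dropped <- nrow(envsel$pruning$dropped)
    log$env_variables_selected <- length(envsel$selection$selected)

    # -- envfit
    fit <- run_stage_safely("envfit", {
      env_vectors(ord, envsel$env, permutations = config$envfit$permutations,
                  seed = stage_seed(config, 7))
    })
    write.csv(fit$vectors, file.path(out, "envfit.csv"), row.names = FALSE)
    outputs$envfit <- file.path(out, "envfit.csv")
  } else {
    message("no environmental table supplied; environment and envfit stages skipped")
  }

  # -- exclusive species + tracks
  trk <- run_stage_safely("tracks", {
    exc <- exclusive_species(ct, reg$assignment)
    recs <- curate_records(dat$occ)$records
    tracks <- suppressMessages(biogeographic_tracks(recs, exc))
    list(exclusive = exc, tracks = tracks)
  })
  exc_df <- data.frame(
    species = unlist(trk$exclusive, use.names = FALSE),
    district = rep(names(trk$exclusive), lengths(trk$exclusive))
  )
  write.csv(exc_df, file.path(out, "exclusive_species.csv"), row.names = FALSE)
  if (length(trk$tracks))
    write_tracks_geojson(trk$tracks, file.path(out, "tracks.geojson"))
  outputs$tracks <- file.path(out, c("exclusive_species.csv",
                                     if (length(trk$tracks)) "tracks.geojson"))
  log$exclusive_species <- lapply(trk$exclusive, length)

  # -- manifest
  cfg_yaml <- file.path(out, "config.yaml")
  yaml::write_yaml(config_to_plain(config), cfg_yaml)
  manifest <- list(
    package = "phytodistricts",
    version = as.character(utils::packageVersion("phytodistricts")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = stats::setNames(as.list(sapply(1:7, stage_seed, cfg = config)),
                                  c("landscape", "occurrences", "env", "mrpp",
                                    "nmds", "rda", "envfit")),
    config_hash = unname(tools::md5sum(cfg_yaml)),
    log = log,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(cell_table = ct, turnover = d, regionalization = reg,
                 ordination = ord, axis_maps = am, environment = envsel,
                 envfit = fit, exclusive = trk$exclusive, tracks = trk$tracks,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

config_to_plain <- function(x) {
  # strip S3 classes so the config serializes as plain YAML
  if (is.list(x)) lapply(unclass(x), config_to_plain) else x
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("phytodistricts pipeline result\n")
  cat("  output dir:", x$config$paths$output_dir, "\n")
  cat("  stages:", paste(names(x$manifest$outputs), collapse = ", "), "\n\n")
  print(x$regionalization)
  cat(sprintf("\n  NMDS stress = %.4f (%s)\n", x$ordination$stress,
              x$ordination$stress_quality))
  cat("  selected env predictors:",
      if (length(x$environment$selection$selected))
        paste(x$environment$selection$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Run a single pipeline stage from the previous stage's files
#'
#' Stages read their inputs from the configuration's output directory, so any
#' later stage can be re-run standalone after its predecessors have written
#' their artifacts.
#'
#' @param stage one of `"simulate"`, `"grid"`, `"turnover"`, `"cluster"`,
#'   `"mrpp"`, `"nmds"`, `"env-select"`, `"envfit"`, `"tracks"`.
#' @param config a [pipeline_config()].
#' @return The stage's in-memory result, invisibly (files are written as in
#'   [run_pipeline()]).
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  out <- config$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  get_ct <- function() read_cell_table(out)
  get_d <- function() read_dist_csv(file.path(out, "turnover.csv"))
  get_assignment <- function() read.csv(file.path(out, "districts.csv"),
                                        stringsAsFactors = FALSE)
  res <- switch(
    stage,
    simulate = simulate_dataset(config),
    grid = {
      occ_path <- config$paths$occurrences %||% file.path(out, "occurrences.csv")
      occ <- read_occurrences_csv(occ_path)
      region <- if (!is.null(config$paths$region))
        read_region_geojson(config$paths$region) else NULL
      ct <- grid_occurrences(occ,
                             grid_spec(config$grid$origin, config$grid$cell_size),
                             region = region,
                             min_records = config$grid$min_records,
                             max_ring = config$grid$max_ring)
      write_cell_table(ct, out)
      ct
    },
    turnover = {
      d <- turnover_matrix(incidence_matrix(get_ct()))
      write_dist_csv(d, file.path(out, "turnover.csv"))
      d
    },
    cluster = {
      reg <- regionalize(get_d(), k_groups = config$clustering$k_groups,
                         k_final = config$clustering$k_final,
                         permutations = config$mrpp$permutations,
                         seed = stage_seed(config, 4))
      write_newick(reg$dendrogram, file.path(out, "dendrogram.nwk"))
      write.csv(reg$assignment, file.path(out, "districts.csv"),
                row.names = FALSE)
      reg
    },
    mrpp = {
      a <- get_assignment()
      m <- mrpp_test(get_d(), stats::setNames(a$district, a$cell_id),
                     permutations = config$mrpp$permutations,
                     seed = stage_seed(config, 4))
      jsonlite::write_json(list(observed_delta = m$observed_delta,
                                p_value = m$p_value, A = m$A,
                                permutations = m$permutations),
                           file.path(out, "mrpp.json"),
                           auto_unbox = TRUE, digits = NA)
      m
    },
    nmds = {
      ord <- nmds(get_d(), k = config$nmds$k, restarts = config$nmds$restarts,
                  max_iter = config$nmds$max_iter, tol = config$nmds$tol,
                  seed = stage_seed(config, 5))
      am <- axis_maps(ord, get_assignment())
      write.csv(data.frame(cell_id = rownames(am$scores), am$scores),
                file.path(out, "nmds_scores.csv"), row.names = FALSE)
      ord
    },
    `env-select` = {
      env_path <- config$paths$env %||% file.path(out, "env.csv")
      env <- read.csv(env_path, stringsAsFactors = FALSE)
      ct <- get_ct()
      env <- env[env$cell_id %in% ct$cells$cell_id, ]
      pr <- prune_collinear(env, config$rda$collinearity_threshold)
      envz <- standardize_env(pr$env)
      Yz <- scale(incidence_matrix(ct))
      Yz <- Yz[, !is.na(colSums(Yz)), drop = FALSE]
      fs <- forward_select(Yz, envz, permutations = config$rda$permutations,
                           alpha = config$rda$alpha,
                           seed = stage_seed(config, 6))
      write.csv(fs$steps, file.path(out, "rda_steps.csv"), row.names = FALSE)
      fs
    },
    envfit = {
      sc <- read.csv(file.path(out, "nmds_scores.csv"), row.names = 1)
      env_path <- config$paths$env %||% file.path(out, "env.csv")
      env <- read.csv(env_path, stringsAsFactors = FALSE)
      env <- env[env$cell_id %in% rownames(sc), ]
      env <- standardize_env(
        prune_collinear(env, config$rda$collinearity_threshold)$env)
      fit <- env_vectors(as.matrix(sc), env,
                         permutations = config$envfit$permutations,
                         seed = stage_seed(config, 7))
      write.csv(fit$vectors, file.path(out, "envfit.csv"), row.names = FALSE)
      fit
    },
    tracks = {
      ct <- get_ct()
      exc <- exclusive_species(ct, get_assignment())
      occ_path <- config$paths$occurrences %||% file.path(out, "occurrences.csv")
      recs <- curate_records(read_occurrences_csv(occ_path))$records
      tracks <- suppressMessages(biogeographic_tracks(recs, exc))
      if (length(tracks))
        write_tracks_geojson(tracks, file.path(out, "tracks.geojson"))
      list(exclusive = exc, tracks = tracks)
    },
    stop("unknown stage: ", stage)
  )
  invisible(res)
}
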