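#' Validate and normalize a pipeline configuration
#'
#' Fills every missing field with the reference defaults — bounding box
#' 113-135 degE / 0-13 degS, topology scan over 4..25 clusters, 1000 training
#' steps with initial neighborhood radius 3, silhouette subsample of 10000
#' points — and rejects unknown or contradictory settings. Normalization is
#' idempotent.
#'
#' @param config Named list; may be empty. Recognized keys: `seed`,
#'   `bbox` (named list `lon_min`, `lon_max`, `lat_min`, `lat_max`),
#'   `scan` (`k_min`, `k_max`), `train` (`steps`, `init_radius`, `init`,
#'   `restarts`), `si_sample_size`, and `synth` (arguments of
#'   [synth_config()] except `seed`).
#' @return Normalized config list of class `seascape_config`.
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "seascape_config")) config <- unclass(config)
  stopifnot(is.list(config))
  known <- c("seed", "bbox", "scan", "train", "si_sample_size", "synth")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  def <- list(
    seed = 1L,
    bbox = list(lon_min = 113, lon_max = 135, lat_min = -13, lat_max = 0),
    scan = list(k_min = 4L, k_max = 25L),
    train = list(steps = 1000L, init_radius = 3, init = "pca_plane",
                 restarts = 4L),
    si_sample_size = 10000,
    synth = list(K = 9, n_rows = 60, n_cols = 60, years = 11,
                 coarse_months = 63, coarse_factor = 3,
                 land_fraction = 0.2, smooth_len = 2)
  )
  merge_block <- function(name) {
    blk <- utils::modifyList(def[[name]], config[[name]] %||% list())
    bad <- setdiff(names(blk), names(def[[name]]))
    if (length(bad)) {
      stop("unknown key(s) in '", name, "': ", paste(bad, collapse = ", "))
    }
    blk
  }
  out <- list(
    seed = as.integer(config$seed %||% def$seed),
    bbox = merge_block("bbox"),
    scan = merge_block("scan"),
    train = merge_block("train"),
    si_sample_size = config$si_sample_size %||% def$si_sample_size,
    synth = merge_block("synth")
  )
  if (out$scan$k_min > out$scan$k_max) {
    stop("scan$k_min (", out$scan$k_min, ") exceeds scan$k_max (",
         out$scan$k_max, ")")
  }
  if (out$bbox$lon_min >= out$bbox$lon_max ||
      out$bbox$lat_min >= out$bbox$lat_max) {
    stop("bbox min edges must be below max edges")
  }
  structure(out, class = "seascape_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full bioregionalization pipeline on a synthetic seascape
#'
#' End to end: simulate seeded inputs, derive the six climatological
#' variables (long-term means; climatological SST extremes), regrid the
#' coarse fields bicubically, crop to the bounding box, screen collinearity,
#' range-standardize, scan lattice topologies with the batch SOM, select the
#' best partition by mean silhouette, and characterize the classes. If
#' `out_dir` is given, all artifacts (variable grids, feature table, scan
#' table, class map, class summary, neuron diagnostics, manifest with file
#' hashes) are written there.
#'
#' @param config A config list for [validate_config()].
#' @param out_dir Optional output directory.
#' @param verbose Print per-scenario progress.
#' @return List of class `seascape_run`: `config`, `sim` (the synthetic
#'   truth), `grids` (six derived variable grids), `table_raw`, `table_std`,
#'   `collinearity`, `scan`, `best`, `summary`, `ranges`, and (when written)
#'   `manifest`.
#' @export
run_seascape <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  cfg <- validate_config(config)
  sim <- synth_seascape(do.call(synth_config, c(cfg$synth, list(seed = cfg$seed))))

  # climatological variable derivation
  avg_sst <- longterm_mean(sim$sst_stack)
  ext <- climatology_extremes(monthly_climatology(sim$sst_stack))
  chla <- longterm_mean(sim$chla_stack)
  cur_coarse <- longterm_mean(sim$currents_stack)
  sal_coarse <- longterm_mean(sim$salinity_stack)
  currents <- resample_bicubic(cur_coarse, sim$geo, target_mask = sim$sea_mask)
  salinity <- resample_bicubic(sal_coarse, sim$geo, target_mask = sim$sea_mask)
  grids <- list(avg_sst = avg_sst, max_sst = ext$max, min_sst = ext$min,
                chla = chla, currents = currents, salinity = salinity)
  for (v in names(grids)) grids[[v]]$varname <- v
  bb <- cfg$bbox
  grids <- lapply(grids, crop_grid, lon_min = bb$lon_min, lon_max = bb$lon_max,
                  lat_min = bb$lat_min, lat_max = bb$lat_max)
  sea_grid <- raster_grid(ifelse(sim$sea_mask, 1, NA_real_), sim$geo,
                          mask = sim$sea_mask)
  sea_crop <- crop_grid(sea_grid, bb$lon_min, bb$lon_max, bb$lat_min, bb$lat_max)

  table_raw <- build_feature_table(grids, sea_crop$mask)
  collin <- withCallingHandlers(
    assess_collinearity(table_raw),
    warning = function(w) {
      if (verbose) message(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  table_std <- range_standardize(table_raw)

  scan <- run_scan(
    table_std,
    scenarios = enumerate_scenarios(cfg$scan$k_min, cfg$scan$k_max),
    config = train_config(steps = cfg$train$steps,
                          init_radius = cfg$train$init_radius,
                          init = cfg$train$init, seed = cfg$seed),
    sample_size = cfg$si_sample_size, seed = cfg$seed,
    restarts = cfg$train$restarts, verbose = verbose
  )
  best <- select_best(scan)
  interest <- synth_interest_mask(attr(table_raw, "geo"))
  summary <- class_summary(table_raw, best$labels, interest_mask = interest)
  ranges <- summary_ranges(summary)

  run <- structure(
    list(config = cfg, sim = sim, grids = grids,
         table_raw = table_raw, table_std = table_std,
         collinearity = collin, scan = scan, best = best,
         summary = summary, ranges = ranges, manifest = NULL),
    class = "seascape_run"
  )
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' @export
print.seascape_run <- function(x, ...) {
  cat(sprintf(
    "<seascape_run> seed %d: best %d x %d (k = %d), mean SI = %.4f, %d classes\n",
    x$config$seed, x$best$x, x$best$y, x$best$k, x$best$mean_si,
    x$best$n_nonempty
  ))
  invisible(x)
}

# Serialize every pipeline artifact under `dir` and return the manifest.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  for (v in names(run$grids)) {
    add(write_grid(run$grids[[v]], file.path(dir, paste0(v, ".asc")),
                   integer = FALSE))
  }
  readr::write_csv(run$table_raw, file.path(dir, "feature_table.csv"))
  add(file.path(dir, "feature_table.csv"))
  params <- attr(run$table_std, "standardization")
  jsonlite::write_json(params, file.path(dir, "standardization.json"),
                       dataframe = "rows", digits = NA)
  add(file.path(dir, "standardization.json"))
  scan_tbl <- dplyr::select(tibble::as_tibble(run$scan), "k", "x", "y",
                            "n_nonempty", "mean_si", "flagged")
  readr::write_csv(scan_tbl, file.path(dir, "scan.csv"))
  add(file.path(dir, "scan.csv"))
  model <- run$best$model
  jsonlite::write_json(
    list(x = model$lattice$x, y = model$lattice$y,
         steps = model$config$steps, init_radius = model$config$init_radius,
         init = model$config$init, seed = model$config$seed,
         iterations = model$iterations, weights = model$weights),
    file.path(dir, "som_model.json"), digits = NA, auto_unbox = TRUE
  )
  add(file.path(dir, "som_model.json"))
  add(export_class_map(run$best$labels, run$table_raw,
                       file.path(dir, "class_map.asc")))
  readr::write_csv(run$summary, file.path(dir, "class_summary.csv"))
  add(file.path(dir, "class_summary.csv"))
  readr::write_csv(neighbor_weight_distances(model),
                   file.path(dir, "neighbor_distances.csv"))
  add(file.path(dir, "neighbor_distances.csv"))
  readr::write_csv(input_weight_planes(model),
                   file.path(dir, "weight_planes.csv"))
  add(file.path(dir, "weight_planes.csv"))
  manifest <- list(
    package = "seascaper",
    version = as.character(utils::packageVersion("seascaper")),
    seed = run$config$seed,
    best = list(x = run$best$x, y = run$best$y, k = run$best$k,
                mean_si = run$best$mean_si),
    files = tibble::tibble(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A config list (for writing).
#' @return `read_config()`: a normalized `seascape_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}
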