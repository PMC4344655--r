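#' @importFrom rlang .data
NULL

#' The six biophysical variables, in fixed column order
#'
#' Long-term mean SST, climatological maximum and minimum monthly SST,
#' long-term mean chlorophyll a, current speed, and salinity.
#'
#' @format Character vector of length 6.
#' @export
seascape_variables <- c("avg_sst", "max_sst", "min_sst",
                        "chla", "currents", "salinity")

#' Units of the six biophysical variables
#' @format Named character vector.
#' @export
seascape_units <- c(avg_sst = "degC", max_sst = "degC", min_sst = "degC",
                    chla = "mg/m^3", currents = "m/s", salinity = "PSU")

# Separable Gaussian smoothing with reflected edges; len = 0 is the identity.
gaussian_smooth <- function(m, len) {
  if (len <= 0) return(m)
  half <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(seq(-half, half), sd = len)
  k <- k / sum(k)
  smooth_1d <- function(x) {
    n <- length(x)
    # pad by edge clamping, then valid convolution
    padded <- x[pmin(pmax(seq(1 - half, n + half), 1), n)]
    stats::convolve(padded, rev(k), type = "filter")
  }
  m2 <- apply(m, 2, smooth_1d)
  t(apply(m2, 1, smooth_1d))
}

# White noise smoothed to correlation length `len`, rescaled to sd `sd`.
smoothed_noise <- function(n_rows, n_cols, sd, len) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- gaussian_smooth(z, len)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z * sd
}

#' Generate a blob-like sea/land mask
#'
#' Thresholds a spatially smoothed Gaussian noise field at the requested
#' quantile, giving contiguous land blobs reminiscent of islands. The achieved
#' land fraction matches the request up to grid-cell rounding.
#'
#' @param geo A [grid_geo()].
#' @param land_fraction Fraction of cells to mark as land, in `[0, 1)`.
#' @param seed Integer seed; the mask is reproducible given (geo, fraction, seed).
#' @return Logical matrix, `TRUE` = sea.
#' @export
synth_land_mask <- function(geo, land_fraction, seed) {
  stopifnot(land_fraction >= 0, land_fraction < 1)
  if (land_fraction == 0) return(matrix(TRUE, geo$n_rows, geo$n_cols))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  len <- max(2, round(min(geo$n_rows, geo$n_cols) / 12))
  field <- smoothed_noise(geo$n_rows, geo$n_cols, sd = 1, len = len)
  thr <- stats::quantile(field, 1 - land_fraction, names = FALSE)
  field <= thr
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plant K contiguous regimes on a grid
#'
#' Draws `K` seed cells uniformly (without replacement) among sea cells, then
#' labels every sea cell by its nearest seed (Euclidean distance in cell
#' coordinates, ties to the lowest seed index). This Voronoi construction
#' yields irregular, spatially contiguous regions resembling oceanographic
#' provinces.
#'
#' @param geo A [grid_geo()].
#' @param K Number of regimes (`K >= 1`, at most the number of sea cells).
#' @param seed Integer seed.
#' @param sea_mask Optional logical matrix (`TRUE` = sea); default all sea.
#' @return Integer matrix of labels `1..K` (NA on land).
#' @export
plant_regions <- function(geo, K, seed, sea_mask = NULL) {
  if (is.null(sea_mask)) sea_mask <- matrix(TRUE, geo$n_rows, geo$n_cols)
  sea_idx <- which(sea_mask)
  if (K > length(sea_idx)) stop("K exceeds the number of sea cells")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample(sea_idx, K)
  sr <- (seeds - 1L) %% geo$n_rows + 1L
  sc <- (seeds - 1L) %/% geo$n_rows + 1L
  rows <- (sea_idx - 1L) %% geo$n_rows + 1L
  cols <- (sea_idx - 1L) %/% geo$n_rows + 1L
  d2 <- outer(rows, sr, `-`)^2 + outer(cols, sc, `-`)^2
  lab <- max.col(-d2, ties.method = "first")
  out <- matrix(NA_integer_, geo$n_rows, geo$n_cols)
  out[sea_idx] <- lab
  out
}

#' Default regime mean signatures
#'
#' Builds a `K x 6` table of distinct class means in physical units. Each
#' variable receives `K` evenly spaced levels across a realistic tropical-
#' seascape range (SST 26.6-29.1 degC, chlorophyll a 0.2-1.6 mg/m^3 spaced on
#' the log scale, currents 0.06-0.33 m/s, salinity 32.5-34.6 PSU); the levels
#' are permuted independently per variable so regimes are decorrelated across
#' variables while keeping a guaranteed per-variable spacing. Among 200
#' seeded permutation draws, the one maximizing the smallest pairwise
#' distance between signature vectors (in range-normalized space) is kept, so
#' no two regimes end up markedly closer than the rest — the planted
#' structure is then identifiable rather than hinging on one near-duplicate
#' pair. Max/Min SST are placed symmetrically about Avg SST via a per-class
#' seasonal amplitude (0.9-2.0 degC), so a sinusoidal seasonal cycle can
#' reproduce them exactly.
#'
#' @param K Number of regimes.
#' @param seed Integer seed controlling the permutations.
#' @return Tibble with columns `class` and the six [seascape_variables].
#' @export
default_class_means <- function(K, seed) {
  stopifnot(K >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lev <- function() {
    v <- if (K == 1) 0.5 else seq(0, 1, length.out = K)
    sample(v)
  }
  best <- NULL
  best_sep <- -Inf
  for (draw in seq_len(if (K == 1) 1 else 200)) {
    # unit-scale signature matrix: avg, amplitude, log-chla, currents, salinity
    U <- cbind(lev(), lev(), lev(), lev(), lev())
    # separation measured on the six derived variables, range-normalized
    V <- cbind(U[, 1], (U[, 1] + U[, 2]) / 2, (U[, 1] - U[, 2] + 1) / 2,
               U[, 3], U[, 4], U[, 5])
    d <- if (K == 1) Inf else min(stats::dist(V))
    if (d > best_sep) {
      best_sep <- d
      best <- U
    }
  }
  rescale <- function(u, lo, hi) lo + u * (hi - lo)
  avg <- rescale(best[, 1], 26.6, 29.1)
  amp <- rescale(best[, 2], 0.9, 2.0)
  tibble::tibble(
    class = seq_len(K),
    avg_sst = avg,
    max_sst = avg + amp,
    min_sst = avg - amp,
    chla = exp(rescale(best[, 3], log(0.2), log(1.6))),
    currents = rescale(best[, 4], 0.06, 0.33),
    salinity = rescale(best[, 5], 32.5, 34.6)
  )
}

# Per-variable noise SD at 1/5 of the smallest between-class mean gap, the
# separation regime the recovery analyses assume. Chla noise acts on the log
# scale, so its gap is measured there too.
default_noise_sd <- function(class_means) {
  vars <- seascape_variables
  sds <- vapply(vars, function(v) {
    x <- class_means[[v]]
    if (v == "chla") x <- log(x)
    if (length(x) < 2) return(0.05)
    min(diff(sort(x))) / 5
  }, numeric(1))
  names(sds) <- vars
  sds
}

#' Synthetic-seascape configuration
#'
#' Collects every knob of the generator with the defaults used throughout:
#' a 60 x 60 grid over 113-135 degE, 0-13 degS; 9 planted regimes; 11 years of
#' monthly SST-like data; about 5 years of coarse current/salinity-like data
#' at 1/3 resolution; land fraction 0.2; spatial correlation length 2 cells;
#' per-variable regime noise at 1/5 of the smallest between-class gap.
#'
#' @param K Number of planted regimes.
#' @param seed Integer seed driving every random draw.
#' @param n_rows,n_cols Fine-grid shape.
#' @param years Years of fine-grid monthly data.
#' @param coarse_months Months of coarse-grid data.
#' @param coarse_factor Fine-to-coarse block size (coarse cell = factor^2 fine cells).
#' @param land_fraction Fraction of land cells.
#' @param smooth_len Spatial correlation length of regime noise, in cells.
#' @param noise_sd Optional named per-variable noise SDs; default gap/5.
#' @param monthly_noise_sd Named SDs of the month-to-month noise added to the
#'   stacks (SST in degC, chla in mg/m^3, currents in m/s, salinity in PSU).
#' @param class_means Optional `K x 6` tibble overriding [default_class_means()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(K = 9, seed = 1, n_rows = 60, n_cols = 60,
                         years = 11, coarse_months = 63, coarse_factor = 3,
                         land_fraction = 0.2, smooth_len = 2,
                         noise_sd = NULL,
                         monthly_noise_sd = c(sst = 0.3, chla = 0.05,
                                              currents = 0.03, salinity = 0.05),
                         class_means = NULL) {
  stopifnot(K >= 2 || !is.null(class_means), years >= 1, land_fraction < 1)
  if (is.null(class_means)) class_means <- default_class_means(K, seed)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(class_means)
  structure(
    list(K = K, seed = seed, n_rows = n_rows, n_cols = n_cols, years = years,
         coarse_months = coarse_months, coarse_factor = coarse_factor,
         land_fraction = land_fraction, smooth_len = smooth_len,
         noise_sd = noise_sd, monthly_noise_sd = monthly_noise_sd,
         class_means = class_means),
    class = "synth_config"
  )
}

#' Generate the six regime fields
#'
#' Each pixel's value is the mean of its planted regime plus spatially
#' smoothed Gaussian noise (white noise convolved with a Gaussian kernel of
#' scale `smooth_len`, rescaled to the per-variable `noise_sd`). Chlorophyll a
#' is generated on the log scale and exponentiated (with the lognormal mean
#' correction), keeping it positive and right-skewed. Max SST is built as
#' Min SST plus a non-negative gap, so Max >= Min holds at every pixel.
#'
#' @param labels Integer regime-label matrix from [plant_regions()].
#' @param class_means Tibble from [default_class_means()] (or same shape).
#' @param geo A [grid_geo()].
#' @param noise_sd Named per-variable noise SDs (chla on the log scale).
#' @param smooth_len Spatial correlation length in cells.
#' @param seed Integer seed.
#' @return Named list of six [raster_grid()]s in [seascape_variables] order.
#' @export
synth_variable_fields <- function(labels, class_means, geo, noise_sd,
                                  smooth_len = 2, seed = 1) {
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mask <- !is.na(labels)
  nr <- geo$n_rows
  nc <- geo$n_cols
  lookup <- function(v) {
    out <- matrix(NA_real_, nr, nc)
    out[mask] <- class_means[[v]][labels[mask]]
    out
  }
  noise <- function(v) smoothed_noise(nr, nc, noise_sd[[v]], smooth_len)
  fields <- list()
  fields$avg_sst <- lookup("avg_sst") + noise("avg_sst")
  min_f <- lookup("min_sst") + noise("min_sst")
  gap <- pmax(lookup("max_sst") - lookup("min_sst") + noise("max_sst"), 0)
  fields$min_sst <- min_f
  fields$max_sst <- min_f + gap
  sd_chla <- noise_sd[["chla"]]
  fields$chla <- exp(log(lookup("chla")) + noise("chla") - sd_chla^2 / 2)
  fields$currents <- pmax(lookup("currents") + noise("currents"), 0)
  fields$salinity <- lookup("salinity") + noise("salinity")
  fields <- fields[seascape_variables]
  purrr::imap(fields, function(m, v) {
    m[!mask] <- NA_real_
    raster_grid(m, geo, mask = mask, units = seascape_units[[v]], varname = v)
  })
}

#' Generate a monthly stack with a sinusoidal seasonal cycle
#'
#' Month `m` of every year equals `annual_mean + amplitude * sin(2*pi*(m-1)/12)
#' + noise`. The sinusoid sums to zero over any whole year, so the long-term
#' mean of a noiseless stack equals `annual_mean` exactly, and the sampled
#' phases attain +/-1, so the climatological extremes are `annual_mean +/-
#' amplitude`.
#'
#' @param annual_mean A [raster_grid()] with the per-pixel annual mean.
#' @param amplitude Seasonal amplitude: a scalar (degC) or a matrix matching
#'   the grid for per-pixel amplitudes.
#' @param years Number of years (12 months each).
#' @param noise_sd SD of white month-to-month noise.
#' @param seed Integer seed.
#' @param start_year First calendar year of the stack.
#' @return A [monthly_stack()] of `12 * years` grids.
#' @export
synth_monthly_stack <- function(annual_mean, amplitude, years, noise_sd = 0,
                                seed = 1, start_year = 2002) {
  stopifnot(inherits(annual_mean, "raster_grid"), years >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  geo <- annual_mean$geo
  mask <- annual_mean$mask
  grids <- list()
  yy <- integer(0)
  mm <- integer(0)
  for (y in seq_len(years)) {
    for (m in 1:12) {
      v <- annual_mean$values + amplitude * sin(2 * pi * (m - 1) / 12)
      if (noise_sd > 0) {
        v <- v + matrix(stats::rnorm(length(v), sd = noise_sd), nrow(v))
      }
      v[!mask] <- NA_real_
      grids[[length(grids) + 1L]] <-
        raster_grid(v, geo, mask = mask, units = annual_mean$units,
                    varname = annual_mean$varname)
      yy <- c(yy, start_year + y - 1L)
      mm <- c(mm, m)
    }
  }
  monthly_stack(grids, yy, mm)
}

# Block-average a fine grid to a coarser geometry (factor x factor blocks);
# a coarse cell is valid when any of its fine cells is, and averages over the
# valid ones. Used to emulate the coarser model-grid variables.
block_aggregate <- function(grid, factor) {
  g <- grid$geo
  nr <- g$n_rows %/% factor
  nc <- g$n_cols %/% factor
  v <- grid$values[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  msk <- grid$mask[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  out <- matrix(NA_real_, nr, nc)
  out_mask <- matrix(FALSE, nr, nc)
  ri <- (seq_len(nr * factor) - 1L) %/% factor + 1L
  ci <- (seq_len(nc * factor) - 1L) %/% factor + 1L
  grp <- outer(ri, ci, function(a, b) (b - 1L) * nr + a)
  sums <- tapply(ifelse(msk, v, 0), grp, sum)
  cnts <- tapply(as.numeric(msk), grp, sum)
  idx <- as.integer(names(sums))
  out[idx] <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  out_mask[idx] <- cnts > 0
  coarse_geo <- grid_geo(g$lon_min, g$lon_min + nc * factor * g$dx,
                         g$lat_max - nr * factor * g$dy, g$lat_max,
                         n_rows = nr, n_cols = nc)
  raster_grid(out, coarse_geo, mask = out_mask,
              units = grid$units, varname = grid$varname)
}

#' Generate a complete synthetic seascape
#'
#' Produces everything the analysis pipeline consumes, in one seeded draw:
#' a blob-like land mask; `K` planted contiguous regimes with distinct
#' six-variable signatures; fine-grid monthly SST and chlorophyll a stacks
#' (the SST stack carries a per-pixel sinusoidal seasonal cycle whose
#' amplitude encodes the planted Max/Min SST); and coarse-grid current and
#' salinity stacks at 1/3 the fine resolution, exercising the bicubic
#' regridding step.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_seascape`: `geo`, `sea_mask`, `truth`
#'   (list with `labels`, `class_means`, `seed`), `fields` (the six noiseless-
#'   regime fields), `sst_stack`, `chla_stack`, `currents_stack`,
#'   `salinity_stack`, and `config`.
#' @export
synth_seascape <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  geo <- grid_geo(113, 135, -13, 0, n_rows = cfg$n_rows, n_cols = cfg$n_cols)
  sea <- synth_land_mask(geo, cfg$land_fraction, seed = cfg$seed)
  labels <- plant_regions(geo, cfg$K, seed = cfg$seed + 1L, sea_mask = sea)
  fields <- synth_variable_fields(labels, cfg$class_means, geo,
                                  noise_sd = cfg$noise_sd,
                                  smooth_len = cfg$smooth_len,
                                  seed = cfg$seed + 2L)
  # per-pixel seasonal amplitude reproducing the planted max/min SST exactly
  amp <- (fields$max_sst$values - fields$min_sst$values) / 2
  center <- (fields$max_sst$values + fields$min_sst$values) / 2
  sst_base <- raster_grid(center, geo, mask = sea, units = "degC",
                          varname = "sst")
  sst_stack <- synth_monthly_stack(sst_base, amp, years = cfg$years,
                                   noise_sd = cfg$monthly_noise_sd[["sst"]],
                                   seed = cfg$seed + 3L)
  chla_stack <- synth_monthly_stack(fields$chla, 0, years = cfg$years,
                                    noise_sd = cfg$monthly_noise_sd[["chla"]],
                                    seed = cfg$seed + 4L)
  cur_coarse <- block_aggregate(fields$currents, cfg$coarse_factor)
  sal_coarse <- block_aggregate(fields$salinity, cfg$coarse_factor)
  n_years_coarse <- ceiling(cfg$coarse_months / 12)
  clip_stack <- function(st, n) {
    monthly_stack(st$grids[seq_len(n)], st$time$year[seq_len(n)],
                  st$time$month[seq_len(n)])
  }
  currents_stack <- clip_stack(
    synth_monthly_stack(cur_coarse, 0, years = n_years_coarse,
                        noise_sd = cfg$monthly_noise_sd[["currents"]],
                        seed = cfg$seed + 5L, start_year = 2008),
    cfg$coarse_months
  )
  salinity_stack <- clip_stack(
    synth_monthly_stack(sal_coarse, 0, years = n_years_coarse,
                        noise_sd = cfg$monthly_noise_sd[["salinity"]],
                        seed = cfg$seed + 6L, start_year = 2008),
    cfg$coarse_months
  )
  structure(
    list(geo = geo, sea_mask = sea,
         truth = list(labels = labels, class_means = cfg$class_means,
                      seed = cfg$seed),
         fields = fields,
         sst_stack = sst_stack, chla_stack = chla_stack,
         currents_stack = currents_stack, salinity_stack = salinity_stack,
         config = cfg),
    class = "synth_seascape"
  )
}

#' Stand-in seascape-of-interest mask
#'
#' An elliptical sub-region of the grid used as the area-of-interest mask for
#' percent-area summaries. This is a synthetic stand-in for a real seascape
#' polygon and carries no geographic meaning.
#'
#' @param geo A [grid_geo()].
#' @param shrink Semi-axes of the ellipse as a fraction of the half-extent.
#' @return Logical matrix, `TRUE` inside the region of interest.
#' @export
synth_interest_mask <- function(geo, shrink = 0.85) {
  lons <- grid_lons(geo)
  lats <- grid_lats(geo)
  cx <- (geo$lon_min + geo$lon_max) / 2
  cy <- (geo$lat_min + geo$lat_max) / 2
  rx <- (geo$lon_max - geo$lon_min) / 2 * shrink
  ry <- (geo$lat_max - geo$lat_min) / 2 * shrink
  outer(lats, lons, function(la, lo) ((lo - cx) / rx)^2 + ((la - cy) / ry)^2 <= 1)
}
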