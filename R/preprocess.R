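# Cubic-convolution kernel (separable bicubic), parameter a = -0.5
# (Catmull-Rom): exact on constant and linear fields, C1-smooth.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# 1-D interpolation weight matrix: rows = target coordinates (in source
# fractional index units, 1-based at cell centers), cols = source cells.
# Support indices are clamped at the edges (edge-value extension).
cubic_weights <- function(u, n_src, a = -0.5) {
  W <- matrix(0, length(u), n_src)
  j0 <- floor(u)
  for (off in -1:2) {
    j <- j0 + off
    w <- cubic_kernel(u - j, a)
    jc <- pmin(pmax(j, 1L), n_src)
    for (i in seq_along(u)) W[i, jc[i]] <- W[i, jc[i]] + w[i]
  }
  W
}

# Brute-force nearest-valid fill (ties to the first cell in column-major
# order). Used to pre-fill land cells before interpolation so nodata does not
# bleed into coastal estimates; source grids are coarse, so this is cheap.
fill_nearest <- function(values, mask) {
  if (all(mask) || !any(mask)) return(values)
  nr <- nrow(values)
  valid <- which(mask)
  vr <- (valid - 1L) %% nr + 1L
  vc <- (valid - 1L) %/% nr + 1L
  hole <- which(!mask)
  hr <- (hole - 1L) %% nr + 1L
  hc <- (hole - 1L) %/% nr + 1L
  for (i in seq_along(hole)) {
    d2 <- (vr - hr[i])^2 + (vc - hc[i])^2
    values[hole[i]] <- values[valid[which.min(d2)]]
  }
  values
}

#' Bicubic resampling of a raster onto a target geometry
#'
#' Separable cubic-convolution interpolation (kernel parameter `a = -0.5`)
#' evaluated at the target cell centers — the step that brings coarse model
#' fields onto the fine satellite grid. Invalid source cells are pre-filled
#' with their nearest valid value so coastal interpolation is not contaminated
#' by the nodata sentinel, and the result is re-masked by `target_mask`.
#'
#' @param grid Source [raster_grid()].
#' @param target Target [grid_geo()]; must lie within the source extent
#'   (edge clamping tolerates boundary cells).
#' @param target_mask Optional logical matrix at target resolution
#'   (`TRUE` = sea). Default: all valid.
#' @param a Cubic kernel parameter.
#' @return A [raster_grid()] on `target`.
#' @export
resample_bicubic <- function(grid, target, target_mask = NULL, a = -0.5) {
  stopifnot(inherits(grid, "raster_grid"), inherits(target, "grid_geo"))
  src <- grid$geo
  if (target$lon_min < src$lon_min - src$dx ||
      target$lon_max > src$lon_max + src$dx ||
      target$lat_min < src$lat_min - src$dy ||
      target$lat_max > src$lat_max + src$dy) {
    stop("target extent is not covered by the source grid")
  }
  v <- fill_nearest(grid$values, grid$mask)
  # fractional source indices of target cell centers
  u_col <- (grid_lons(target) - src$lon_min) / src$dx + 0.5
  u_row <- (src$lat_max - grid_lats(target)) / src$dy + 0.5
  Wr <- cubic_weights(u_row, src$n_rows, a)
  Wc <- cubic_weights(u_col, src$n_cols, a)
  out <- Wr %*% v %*% t(Wc)
  if (is.null(target_mask)) {
    target_mask <- matrix(TRUE, target$n_rows, target$n_cols)
  }
  out[!target_mask] <- NA_real_
  raster_grid(out, target, mask = target_mask,
              units = grid$units, varname = grid$varname)
}

#' Assemble the pixel-by-variable feature table
#'
#' Scans the grid row-major (north to south, west to east) and keeps the
#' cells valid in the sea mask and in all six variable grids; one tibble row
#' per usable sea pixel.
#'
#' @param grids Named list of six co-registered [raster_grid()]s; names must
#'   be the [seascape_variables].
#' @param sea_mask Logical matrix (`TRUE` = sea), co-registered with the grids.
#' @return Tibble with columns `row`, `col`, `lon`, `lat` and the six
#'   variables, carrying the shared geometry in `attr(, "geo")`.
#' @export
build_feature_table <- function(grids, sea_mask) {
  stopifnot(setequal(names(grids), seascape_variables))
  grids <- grids[seascape_variables]
  geo <- check_registered(grids)
  stopifnot(all(dim(sea_mask) == c(geo$n_rows, geo$n_cols)))
  keep <- sea_mask & Reduce(`&`, lapply(grids, function(g) g$mask))
  if (!any(keep)) stop("no usable sea pixels")
  idx <- which(t(keep)) # row-major scan
  col <- (idx - 1L) %% geo$n_cols + 1L
  row <- (idx - 1L) %/% geo$n_cols + 1L
  tbl <- tibble::tibble(
    row = row, col = col,
    lon = grid_lons(geo)[col], lat = grid_lats(geo)[row]
  )
  for (v in seascape_variables) {
    tbl[[v]] <- grids[[v]]$values[cbind(row, col)]
  }
  attr(tbl, "geo") <- geo
  attr(tbl, "standardized") <- FALSE
  tbl
}

#' Scatter a feature-table column back onto its grid
#'
#' Inverse of [build_feature_table()] for one column: cells not present in the
#' table are invalid.
#'
#' @param table Feature table with `row`/`col` columns and a `geo` attribute
#'   (or pass `geo`).
#' @param column Column to scatter (name or numeric vector aligned to rows).
#' @param geo Optional [grid_geo()] override.
#' @return A [raster_grid()].
#' @export
feature_to_grid <- function(table, column, geo = NULL) {
  if (is.null(geo)) geo <- attr(table, "geo")
  stopifnot(inherits(geo, "grid_geo"))
  vals <- if (is.character(column)) table[[column]] else column
  m <- matrix(NA_real_, geo$n_rows, geo$n_cols)
  m[cbind(table$row, table$col)] <- vals
  raster_grid(m, geo, varname = if (is.character(column)) column else NA_character_)
}

#' Pairwise collinearity screen of the feature table
#'
#' Pearson correlations between all variable pairs; pairs at or above the
#' threshold are flagged as collinear. Flagging warns — variables are never
#' dropped automatically.
#'
#' @param table Feature table from [build_feature_table()].
#' @param threshold Absolute correlation that triggers a flag.
#' @return Tibble of variable pairs (`var1`, `var2`, `r`, `flagged`), with the
#'   full 6 x 6 correlation matrix in `attr(, "correlation")`.
#' @export
assess_collinearity <- function(table, threshold = 0.85) {
  vars <- intersect(seascape_variables, names(table))
  stopifnot(length(vars) >= 2, nrow(table) >= 3)
  X <- as.matrix(table[vars])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  C <- stats::cor(X)
  pairs <- utils::combn(vars, 2)
  out <- tibble::tibble(
    var1 = pairs[1, ], var2 = pairs[2, ],
    r = C[t(pairs)],
    flagged = abs(C[t(pairs)]) >= threshold
  )
  if (any(out$flagged)) {
    warning("collinear variable pairs (|r| >= ", threshold, "): ",
            paste(out$var1[out$flagged], out$var2[out$flagged],
                  sep = "~", collapse = ", "))
  }
  attr(out, "correlation") <- C
  out
}

#' Range-standardize the feature table
#'
#' Maps each variable to `[0, 1]` by `(x - min) / (max - min)`, with min/max
#' taken over the table's (cropped, masked) sea pixels, so every variable
#' contributes equally to the clustering. The per-variable parameters are kept
#' for the inverse mapping.
#'
#' @param table Feature table in physical units.
#' @return The standardized tibble; `attr(, "standardization")` holds a tibble
#'   (`variable`, `min`, `max`) and `attr(, "standardized")` is `TRUE`.
#' @seealso [range_unstandardize()]
#' @export
range_standardize <- function(table) {
  vars <- intersect(seascape_variables, names(table))
  params <- tibble::tibble(
    variable = vars,
    min = vapply(vars, function(v) min(table[[v]]), numeric(1)),
    max = vapply(vars, function(v) max(table[[v]]), numeric(1))
  )
  if (any(params$max <= params$min)) {
    stop("constant column(s): ",
         paste(params$variable[params$max <= params$min], collapse = ", "),
         " (degenerate input)")
  }
  out <- table
  for (i in seq_along(vars)) {
    v <- vars[i]
    out[[v]] <- (table[[v]] - params$min[i]) / (params$max[i] - params$min[i])
  }
  attr(out, "standardization") <- params
  attr(out, "standardized") <- TRUE
  attr(out, "geo") <- attr(table, "geo")
  out
}

#' Invert a range standardization
#'
#' @param table Standardized feature table.
#' @param params Optional standardization parameters; default: the table's
#'   `standardization` attribute.
#' @return Tibble in physical units.
#' @export
range_unstandardize <- function(table, params = NULL) {
  if (is.null(params)) params <- attr(table, "standardization")
  stopifnot(!is.null(params))
  out <- table
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    out[[v]] <- table[[v]] * (params$max[i] - params$min[i]) + params$min[i]
  }
  attr(out, "standardized") <- FALSE
  out
}

# Numeric matrix of the six feature columns, rows aligned with the table.
feature_matrix <- function(table) {
  vars <- intersect(seascape_variables, names(table))
  as.matrix(table[vars])
}
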