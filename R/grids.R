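#' Grid geometry for a geolocated raster
#'
#' Describes a regular lon/lat (plate carree) grid by its outer edges and cell
#' counts. Cell sizes are implied: `dx = (lon_max - lon_min) / n_cols`,
#' `dy = (lat_max - lat_min) / n_rows`. Rows are stored north-to-south
#' (row 1 is the northernmost band), matching common level-3 mapped products.
#'
#' @param lon_min,lon_max Western and eastern outer edges, decimal degrees.
#' @param lat_min,lat_max Southern and northern outer edges, decimal degrees.
#' @param n_rows,n_cols Number of cells along latitude and longitude.
#' @return An object of class `grid_geo`.
#' @examples
#' grid_geo(113, 135, -13, 0, n_rows = 60, n_cols = 60)
#' @export
grid_geo <- function(lon_min, lon_max, lat_min, lat_max, n_rows, n_cols) {
  stopifnot(
    is.numeric(lon_min), is.numeric(lon_max), lon_min < lon_max,
    is.numeric(lat_min), is.numeric(lat_max), lat_min < lat_max,
    n_rows >= 1, n_cols >= 1
  )
  structure(
    list(
      lon_min = as.numeric(lon_min), lon_max = as.numeric(lon_max),
      lat_min = as.numeric(lat_min), lat_max = as.numeric(lat_max),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      dx = (lon_max - lon_min) / n_cols,
      dy = (lat_max - lat_min) / n_rows
    ),
    class = "grid_geo"
  )
}

#' @export
print.grid_geo <- function(x, ...) {
  cat(sprintf(
    "<grid_geo> %d x %d cells, lon [%g, %g], lat [%g, %g], cell %g x %g deg\n",
    x$n_rows, x$n_cols, x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$dx, x$dy
  ))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param geo A [grid_geo()].
#' @return `grid_lons()`: vector of `n_cols` longitudes (west to east).
#'   `grid_lats()`: vector of `n_rows` latitudes, north to south so that
#'   element `i` is the latitude of row `i`.
#' @export
grid_lons <- function(geo) {
  geo$lon_min + (seq_len(geo$n_cols) - 0.5) * geo$dx
}

#' @rdname grid_lons
#' @export
grid_lats <- function(geo) {
  geo$lat_max - (seq_len(geo$n_rows) - 0.5) * geo$dy
}

geo_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lon_max - b$lon_max) < tol &&
    abs(a$lat_min - b$lat_min) < tol && abs(a$lat_max - b$lat_max) < tol
}

check_registered <- function(grids) {
  geo <- grids[[1]]$geo
  ok <- vapply(grids, function(g) geo_equal(g$geo, geo), logical(1))
  if (!all(ok)) stop("grids are not co-registered (mismatched geometries)")
  geo
}

#' Geolocated raster field with validity mask
#'
#' Bundles a values matrix with its [grid_geo()] and a logical mask
#' (`TRUE` = valid sea cell). Invalid cells hold `NA`. Units and a variable
#' name travel as metadata.
#'
#' @param values Numeric matrix, `n_rows x n_cols` (row 1 = northernmost).
#' @param geo A [grid_geo()] whose shape matches `values`.
#' @param mask Logical matrix of the same shape; defaults to `!is.na(values)`.
#' @param units Physical units string (e.g. `"degC"`, `"mg/m^3"`).
#' @param varname Variable name string.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, geo, mask = NULL, units = NA_character_,
                        varname = NA_character_) {
  stopifnot(inherits(geo, "grid_geo"), is.matrix(values))
  if (!all(dim(values) == c(geo$n_rows, geo$n_cols))) {
    stop("values shape does not match grid geometry")
  }
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  if (any(mask & !is.finite(values))) {
    stop("non-finite values at cells flagged valid")
  }
  values[!mask] <- NA_real_
  structure(
    list(geo = geo, values = values, mask = mask,
         units = units, varname = varname),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %s [%s], %d x %d cells, %d valid (%.1f%%)\n",
    ifelse(is.na(x$varname), "?", x$varname),
    ifelse(is.na(x$units), "?", x$units),
    x$geo$n_rows, x$geo$n_cols, sum(x$mask), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Crop a raster to a bounding box
#'
#' Keeps exactly the cells whose centers fall inside the box; inclusion is
#' half-open, `[min, max)` on each axis, so adjacent crops never double-count
#' an edge cell. The geometry is updated to the retained cells.
#'
#' @param grid A [raster_grid()].
#' @param lon_min,lon_max,lat_min,lat_max Bounding box, decimal degrees.
#' @return A cropped `raster_grid`.
#' @export
crop_grid <- function(grid, lon_min, lon_max, lat_min, lat_max) {
  stopifnot(inherits(grid, "raster_grid"))
  lons <- grid_lons(grid$geo)
  lats <- grid_lats(grid$geo)
  jj <- which(lons >= lon_min & lons < lon_max)
  ii <- which(lats >= lat_min & lats < lat_max)
  if (length(ii) == 0L || length(jj) == 0L) {
    stop("crop box contains no cell centers")
  }
  g <- grid$geo
  new_geo <- grid_geo(
    lon_min = g$lon_min + (min(jj) - 1) * g$dx,
    lon_max = g$lon_min + max(jj) * g$dx,
    lat_min = g$lat_max - max(ii) * g$dy,
    lat_max = g$lat_max - (min(ii) - 1) * g$dy,
    n_rows = length(ii), n_cols = length(jj)
  )
  raster_grid(grid$values[ii, jj, drop = FALSE], new_geo,
              mask = grid$mask[ii, jj, drop = FALSE],
              units = grid$units, varname = grid$varname)
}

#' Intersect validity masks across co-registered grids
#'
#' A cell is valid in the result iff it is valid in every input grid; this is
#' how land and per-variable gaps are merged into one sea mask.
#'
#' @param grids List of co-registered [raster_grid()] objects.
#' @return Logical matrix.
#' @export
combine_masks <- function(grids) {
  stopifnot(length(grids) >= 1L)
  check_registered(grids)
  Reduce(`&`, lapply(grids, function(g) g$mask))
}

# ---- on-disk format ---------------------------------------------------------
# Arc/Info ASCII grid (.asc): text header (NCOLS/NROWS/XLLCORNER/YLLCORNER/
# CELLSIZE or DX+DY/NODATA_VALUE) then rows north-to-south. A JSON sidecar
# (<path>.json) carries varname and units; the in-memory mask is authoritative,
# on disk it is the single nodata sentinel.

#' Write a raster grid to an ASCII grid file
#'
#' Writes an Arc/Info ASCII grid plus a `<path>.json` sidecar with the
#' variable name and units. Invalid cells are stored as the nodata sentinel.
#' Floating-point values are written with 17 significant digits so a
#' round-trip through [read_grid()] is value-exact; integer-valued grids
#' (e.g. class maps) are written as integers.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path (conventionally `.asc`).
#' @param integer Write values as integers. Default: `TRUE` when every valid
#'   value is a whole number.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, integer = NULL) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  vv <- v[grid$mask]
  if (is.null(integer)) {
    integer <- length(vv) > 0 && all(vv == round(vv)) && all(abs(vv) < 2^31)
  }
  nodata <- -9999
  while (length(vv) > 0 && any(vv == nodata)) nodata <- nodata * 10 - 1
  g <- grid$geo
  header <- c(
    sprintf("NCOLS %d", g$n_cols),
    sprintf("NROWS %d", g$n_rows),
    sprintf("XLLCORNER %.12g", g$lon_min),
    sprintf("YLLCORNER %.12g", g$lat_min),
    if (isTRUE(all.equal(g$dx, g$dy))) {
      sprintf("CELLSIZE %.12g", g$dx)
    } else {
      c(sprintf("DX %.12g", g$dx), sprintf("DY %.12g", g$dy))
    },
    sprintf("NODATA_VALUE %d", as.integer(nodata))
  )
  v[!grid$mask] <- nodata
  fmt <- if (integer) {
    function(row) paste(formatC(row, format = "d"), collapse = " ")
  } else {
    function(row) paste(formatC(row, format = "g", digits = 17), collapse = " ")
  }
  body <- vapply(seq_len(nrow(v)), function(i) fmt(v[i, ]), character(1))
  writeLines(c(header, body), path)
  jsonlite::write_json(
    list(varname = grid$varname, units = grid$units, integer = integer),
    paste0(path, ".json"),
    auto_unbox = TRUE, null = "null", na = "null"
  )
  invisible(path)
}

#' Read a raster grid from an ASCII grid file
#'
#' Inverse of [write_grid()]. Cells equal to the nodata sentinel become
#' invalid (`NA` + mask `FALSE`). If a `<path>.json` sidecar exists, the
#' variable name and units are restored from it.
#'
#' @param path File path.
#' @param variable Optional expected variable name; an error is raised if the
#'   file records a different one.
#' @return A [raster_grid()].
#' @export
read_grid <- function(path, variable = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- toupper(parts[1])
    if (key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER",
                   "CELLSIZE", "DX", "DY", "NODATA_VALUE")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  dx <- if (!is.null(hdr$CELLSIZE)) hdr$CELLSIZE else hdr$DX
  dy <- if (!is.null(hdr$CELLSIZE)) hdr$CELLSIZE else hdr$DY
  if (is.null(dx) || is.null(dy)) stop("malformed ASCII grid header in ", path)
  nr <- as.integer(hdr$NROWS)
  nc <- as.integer(hdr$NCOLS)
  vals <- scan(text = paste(lines[(n_hdr + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("value count does not match header in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- matrix(TRUE, nr, nc)
  if (!is.null(hdr$NODATA_VALUE)) mask <- m != hdr$NODATA_VALUE
  geo <- grid_geo(hdr$XLLCORNER, hdr$XLLCORNER + nc * dx,
                  hdr$YLLCORNER, hdr$YLLCORNER + nr * dy,
                  n_rows = nr, n_cols = nc)
  units <- NA_character_
  varname <- NA_character_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$units)) units <- meta$units
    if (!is.null(meta$varname)) varname <- meta$varname
  }
  if (!is.null(variable) && !is.na(varname) && !identical(variable, varname)) {
    stop("file holds variable '", varname, "', not '", variable, "'")
  }
  raster_grid(m, geo, mask = mask, units = units, varname = varname)
}

#' Time-indexed stack of co-registered monthly grids
#'
#' @param grids List of co-registered [raster_grid()] objects, one per month.
#' @param year,month Integer vectors (same length as `grids`) giving the time
#'   index; `(year, month)` must be strictly increasing.
#' @return An object of class `monthly_stack` with elements `grids`, `time`
#'   (a tibble), and the shared `geo`.
#' @export
monthly_stack <- function(grids, year, month) {
  stopifnot(length(grids) >= 1L, length(year) == length(grids),
            length(month) == length(grids), all(month %in% 1:12))
  geo <- check_registered(grids)
  key <- year * 12 + month
  if (any(diff(key) <= 0)) stop("time index must be strictly increasing")
  structure(
    list(grids = grids,
         time = tibble::tibble(year = as.integer(year),
                               month = as.integer(month)),
         geo = geo),
    class = "monthly_stack"
  )
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf(
    "<monthly_stack> %d months (%d-%02d .. %d-%02d), %d x %d cells\n",
    length(x$grids), x$time$year[1], x$time$month[1],
    utils::tail(x$time$year, 1), utils::tail(x$time$month, 1),
    x$geo$n_rows, x$geo$n_cols
  ))
  invisible(x)
}

#' @export
length.monthly_stack <- function(x) length(x$grids)

#' Write / read a monthly stack as a directory of ASCII grids
#'
#' One `.asc` file per time step plus an `index.json` listing files and
#' `(year, month)` pairs.
#'
#' @param stack A [monthly_stack()].
#' @param dir Directory (created if missing).
#' @return `write_stack()`: `dir`, invisibly. `read_stack()`: a
#'   [monthly_stack()].
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "monthly_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%04d-%02d.asc", stack$time$year, stack$time$month)
  for (i in seq_along(stack$grids)) {
    write_grid(stack$grids[[i]], file.path(dir, files[i]), integer = FALSE)
  }
  jsonlite::write_json(
    list(files = files, year = stack$time$year, month = stack$time$month),
    file.path(dir, "index.json")
  )
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = TRUE)
  grids <- lapply(idx$files, function(f) read_grid(file.path(dir, f)))
  monthly_stack(grids, idx$year, idx$month)
}
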