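#' Long-term per-pixel mean of a time stack
#'
#' Arithmetic mean over time steps with valid data at each pixel. A pixel is
#' declared invalid when it is valid in fewer than `min_frac` of the steps
#' (default one half), which keeps sparsely observed pixels from producing
#' biased means.
#'
#' @param stack A [monthly_stack()].
#' @param min_frac Minimum fraction of valid time steps required per pixel.
#' @return A [raster_grid()] carrying the stack's units, named
#'   `"<varname>_mean"`.
#' @export
longterm_mean <- function(stack, min_frac = 0.5) {
  stopifnot(inherits(stack, "monthly_stack"), length(stack$grids) >= 1)
  n <- length(stack$grids)
  sums <- matrix(0, stack$geo$n_rows, stack$geo$n_cols)
  cnts <- matrix(0L, stack$geo$n_rows, stack$geo$n_cols)
  for (g in stack$grids) {
    sums <- sums + ifelse(g$mask, g$values, 0)
    cnts <- cnts + g$mask
  }
  mask <- cnts >= min_frac * n & cnts > 0
  vals <- ifelse(mask, sums / pmax(cnts, 1L), NA_real_)
  vn <- stack$grids[[1]]$varname
  raster_grid(vals, stack$geo, mask = mask,
              units = stack$grids[[1]]$units,
              varname = if (is.na(vn)) "mean" else paste0(vn, "_mean"))
}

#' Monthly climatology of a stack
#'
#' For each calendar month, the per-pixel mean over every year's realization
#' of that month. The same minimum-coverage rule as [longterm_mean()] applies
#' within each month.
#'
#' @param stack A [monthly_stack()] in which every calendar month occurs at
#'   least once.
#' @param min_frac Minimum fraction of valid years required per pixel, per month.
#' @return A list of class `climatology12`: twelve co-registered
#'   [raster_grid()]s, element `m` being the month-`m` climatology.
#' @export
monthly_climatology <- function(stack, min_frac = 0.5) {
  stopifnot(inherits(stack, "monthly_stack"))
  if (!all(1:12 %in% stack$time$month)) {
    stop("every calendar month must be present at least once")
  }
  months <- lapply(1:12, function(m) {
    sel <- which(stack$time$month == m)
    sub <- monthly_stack(stack$grids[sel], stack$time$year[sel],
                         stack$time$month[sel])
    g <- longterm_mean(sub, min_frac = min_frac)
    g$varname <- sprintf("climatology_m%02d", m)
    g
  })
  structure(months, class = "climatology12")
}

#' Per-pixel extremes of a monthly climatology
#'
#' The per-pixel maximum and minimum over the twelve monthly climatology
#' grids: the climatological extreme variables. A pixel is invalid in the
#' output if it is invalid in any month, since an extreme over a partial year
#' is not comparable.
#'
#' @param clim A `climatology12` from [monthly_climatology()].
#' @return List with elements `max` and `min`, both [raster_grid()]s.
#' @export
climatology_extremes <- function(clim) {
  stopifnot(inherits(clim, "climatology12"), length(clim) == 12)
  geo <- clim[[1]]$geo
  mask <- Reduce(`&`, lapply(clim, function(g) g$mask))
  arr <- vapply(clim, function(g) g$values, clim[[1]]$values)
  mx <- apply(arr, c(1, 2), max)
  mn <- apply(arr, c(1, 2), min)
  mx[!mask] <- NA_real_
  mn[!mask] <- NA_real_
  list(
    max = raster_grid(mx, geo, mask = mask, units = clim[[1]]$units,
                      varname = "climatology_max"),
    min = raster_grid(mn, geo, mask = mask, units = clim[[1]]$units,
                      varname = "climatology_min")
  )
}
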