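#' Per-class summary of a classified seascape
#'
#' The descriptive table of a selected partition: for every class, the
#' percentage of classified sea pixels inside the area-of-interest mask, and
#' the mean and standard deviation of each biophysical variable in raw
#' physical units. Means/SDs are computed over all of a class's pixels
#' (inside or outside the interest area); the percentage uses only in-area
#' pixels, so a class lying wholly outside the area scores 0% while still
#' being characterized.
#'
#' @param raw_table Feature table in physical units (not standardized).
#' @param labels Integer class labels aligned with the table rows.
#' @param interest_mask Optional logical matrix (co-registered with the
#'   table's grid) delimiting the seascape of interest; default: all pixels.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return Tibble of class `class_summary`: `class`, `n_pixels`, `pct_area`,
#'   then `<variable>_mean` and `<variable>_sd` for the six variables.
#' @export
class_summary <- function(raw_table, labels, interest_mask = NULL,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(labels) == nrow(raw_table))
  if (isTRUE(attr(raw_table, "standardized"))) {
    warning("summarizing a standardized table; expected raw physical units")
  }
  in_area <- if (is.null(interest_mask)) {
    rep(TRUE, nrow(raw_table))
  } else {
    interest_mask[cbind(raw_table$row, raw_table$col)]
  }
  n_area <- sum(in_area)
  if (n_area == 0) stop("no classified pixels inside the interest area")
  vars <- intersect(seascape_variables, names(raw_table))
  pop_sd <- function(x) {
    if (sd_type == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
  }
  df <- dplyr::group_by(
    dplyr::mutate(raw_table, .class = labels, .in_area = in_area),
    .data$.class
  )
  out <- dplyr::summarise(
    df,
    n_pixels = dplyr::n(),
    pct_area = 100 * sum(.data$.in_area) / n_area,
    dplyr::across(dplyr::all_of(vars),
                  list(mean = mean, sd = pop_sd),
                  .names = "{.col}_{.fn}"),
    .groups = "drop"
  )
  out <- dplyr::rename(out, class = ".class")
  out <- dplyr::arrange(out, .data$class)
  class(out) <- c("class_summary", class(out))
  out
}

#' Ranges of class means
#'
#' Per-variable minimum, maximum and spread of the class means, optionally
#' over a subset of classes — e.g. contrasting the few classes that dominate
#' the seascape against the full set.
#'
#' @param summary A [class_summary()] (or any tibble with `class` and
#'   `<variable>_mean` columns).
#' @param classes Optional vector of class ids to restrict to.
#' @return Tibble with columns `variable`, `min`, `max`, `range`.
#' @export
summary_ranges <- function(summary, classes = NULL) {
  if (!is.null(classes)) {
    missing_cl <- setdiff(classes, summary$class)
    if (length(missing_cl)) {
      stop("unknown class(es): ", paste(missing_cl, collapse = ", "))
    }
    summary <- summary[summary$class %in% classes, ]
  }
  if (nrow(summary) == 0) stop("empty class subset")
  vars <- seascape_variables[paste0(seascape_variables, "_mean") %in%
                               names(summary)]
  purrr::map_dfr(vars, function(v) {
    m <- summary[[paste0(v, "_mean")]]
    tibble::tibble(variable = v, min = min(m), max = max(m),
                   range = max(m) - min(m))
  })
}

#' Export the class map as an integer raster
#'
#' Writes the selected partition as an integer ASCII grid: class labels at
#' classified cells, nodata at land and unclassified cells.
#'
#' @param labels Integer class labels aligned with `table` rows.
#' @param table Feature table providing the `row`/`col` pixel index.
#' @param geo The [grid_geo()] (default: the table's `geo` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_class_map <- function(labels, table, path, geo = NULL) {
  if (is.null(geo)) geo <- attr(table, "geo")
  stopifnot(inherits(geo, "grid_geo"), length(labels) == nrow(table))
  m <- matrix(NA_real_, geo$n_rows, geo$n_cols)
  m[cbind(table$row, table$col)] <- as.numeric(labels)
  grid <- raster_grid(m, geo, units = "class", varname = "class_map")
  write_grid(grid, path, integer = TRUE)
}

#' Published nine-class reference summary of the Sunda Banda Seascape
#'
#' The printed per-class summary of the published nine-class biophysical
#' delineation of the Sunda Banda Seascape (113-135 degE, 0-13 degS):
#' percentage of the seascape covered by each class and mean +/- SD of the six
#' biophysical variables. Shipped as a plain-text fixture; used to exercise
#' the range arithmetic on real printed values without any download.
#'
#' @return A `class_summary`-shaped tibble (9 classes).
#' @export
sbs_reference_summary <- function() {
  path <- system.file("extdata", "sbs_reference_summary.csv",
                      package = "seascaper", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("class_summary", class(out))
  out
}
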