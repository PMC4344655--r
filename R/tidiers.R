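#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained SOM
#'
#' One row per neuron-variable pair: the weight planes in long form, with
#' lattice layout coordinates for plotting.
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return A tibble: `neuron`, `variable`, `weight`, `px`, `py`.
#' @export
tidy.som_model <- function(x, ...) {
  input_weight_planes(x)
}

#' @rdname tidy.som_model
#' @export
glance.som_model <- function(x, ...) {
  tibble::tibble(
    x = x$lattice$x, y = x$lattice$y, k = x$lattice$k,
    n_features = ncol(x$weights),
    iterations = x$iterations,
    steps = x$config$steps,
    init_radius = x$config$init_radius,
    init = x$config$init
  )
}

#' Tidy a topology scan
#'
#' The scan table without its model/label list-columns: one row per scenario
#' with dimensions, non-empty class count and mean silhouette.
#'
#' @param x A `som_scan` from [run_scan()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.som_scan <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "k", "x", "y", "n_nonempty",
                "mean_si", "flagged")
}

#' @rdname tidy.som_scan
#' @export
glance.som_scan <- function(x, ...) {
  best <- select_best(x)
  tibble::tibble(
    n_scenarios = nrow(x),
    n_flagged = sum(x$flagged),
    best_k = best$k, best_x = best$x, best_y = best$y,
    best_mean_si = best$mean_si
  )
}

#' Tidy a class summary
#'
#' Long form of [class_summary()]: one row per class-variable pair with mean
#' and SD.
#'
#' @param x A `class_summary`.
#' @param ... Unused.
#' @return A tibble: `class`, `pct_area`, `variable`, `mean`, `sd`.
#' @export
tidy.class_summary <- function(x, ...) {
  vars <- seascape_variables[paste0(seascape_variables, "_mean") %in% names(x)]
  purrr::map_dfr(vars, function(v) {
    tibble::tibble(
      class = x$class,
      pct_area = x$pct_area,
      variable = v,
      mean = x[[paste0(v, "_mean")]],
      sd = if (paste0(v, "_sd") %in% names(x)) x[[paste0(v, "_sd")]] else NA_real_
    )
  })
}
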