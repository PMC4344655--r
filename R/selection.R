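#' Enumerate lattice-topology scenarios
#'
#' All unordered factor pairs `{x, y}` with `x * y = k` and `x <= y` for each
#' cluster count `k` in `[k_min, k_max]`, including the linear `1 x k`
#' topologies, sorted by `k` then `x`. The reference scan over 4..25 clusters
#' contains exactly 43 scenarios under this convention.
#'
#' @param k_min,k_max Cluster-count range (defaults 4 and 25).
#' @return Tibble with columns `k`, `x`, `y`.
#' @export
enumerate_scenarios <- function(k_min = 4, k_max = 25) {
  stopifnot(k_min >= 1, k_min <= k_max)
  purrr::map_dfr(seq(k_min, k_max), function(k) {
    x <- seq_len(floor(sqrt(k)))
    x <- x[k %% x == 0]
    tibble::tibble(k = as.integer(k), x = as.integer(x),
                   y = as.integer(k %/% x))
  })
}

#' Silhouette index of a partition
#'
#' For each evaluated point `i`, `a_i` is the mean distance to the other
#' points of its own cluster and `b_i` the smallest mean distance to the
#' points of any other cluster; `SI_i = (b_i - a_i) / max(a_i, b_i)`, in
#' `[-1, 1]`. Points in singleton clusters score 0. Distances are Euclidean
#' in the (standardized) feature space. For large tables the index is
#' evaluated on a seeded uniform subsample, with distances taken within the
#' subsample.
#'
#' @param table Feature table (or plain numeric matrix).
#' @param labels Integer cluster labels aligned to rows.
#' @param sample_size Evaluate on at most this many points (`Inf` = all).
#' @param seed Integer seed for the subsample draw.
#' @return List with `mean` (mean SI over evaluated points), `si` (per-point
#'   values), and `rows` (indices of the evaluated points).
#' @export
silhouette_index <- function(table, labels, sample_size = 10000, seed = 1) {
  X <- if (is.matrix(table)) table else feature_matrix(table)
  stopifnot(length(labels) == nrow(X))
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least 2 non-empty clusters")
  }
  rows <- seq_len(nrow(X))
  if (is.finite(sample_size) && nrow(X) > sample_size) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    rows <- sort(sample(rows, sample_size))
    if (length(unique(labels[rows])) < 2) {
      stop("subsample collapsed to fewer than 2 clusters; increase sample_size")
    }
  }
  Xs <- X[rows, , drop = FALSE]
  ls <- labels[rows]
  D <- as.matrix(stats::dist(Xs))
  cl <- sort(unique(ls))
  ind <- vapply(cl, function(c) as.numeric(ls == c), numeric(length(ls)))
  sums <- D %*% ind
  counts <- colSums(ind)
  own <- match(ls, cl)
  n <- length(ls)
  a <- sums[cbind(seq_len(n), own)] / pmax(counts[own] - 1, 1)
  other <- sweep(sums, 2, counts, `/`)
  other[cbind(seq_len(n), own)] <- Inf
  b <- apply(other, 1, min)
  denom <- pmax(a, b)
  si <- ifelse(denom > 0, (b - a) / denom, 0)
  si[counts[own] == 1] <- 0
  list(mean = mean(si), si = si, rows = rows)
}

#' Run the topology scan
#'
#' For every scenario: build the hexagonal lattice, initialize, train the
#' batch SOM, label every pixel by its best-matching unit, and score the
#' partition with the mean silhouette index. Because batch training is a
#' deterministic descent that can stall in a poor local optimum, each
#' scenario is trained from the deterministic principal-component
#' initialization plus `restarts` seeded data-sample initializations, and
#' the fit with the lowest [quantization_error()] is kept — the restart pick
#' uses the map's own objective, never the silhouette that later ranks
#' scenarios. A scenario whose trained map collapses to fewer than two
#' non-empty classes is recorded with `mean_si = -1` and flagged rather than
#' aborting the scan.
#'
#' @param table Standardized feature table.
#' @param scenarios Tibble from [enumerate_scenarios()].
#' @param config A [train_config()] applied to every scenario.
#' @param sample_size Silhouette subsample size (see [silhouette_index()]).
#' @param seed Seed for the silhouette subsample.
#' @param restarts Number of additional seeded `"sample"`-initialized
#'   training runs per scenario (0 = single deterministic fit).
#' @param verbose Print one progress line per scenario.
#' @return Tibble of class `som_scan`: `k`, `x`, `y`, `n_nonempty`,
#'   `mean_si`, `flagged`, plus list-columns `model` and `labels`.
#' @export
run_scan <- function(table, scenarios = enumerate_scenarios(),
                     config = train_config(), sample_size = 10000, seed = 1,
                     restarts = 4, verbose = FALSE) {
  stopifnot(isTRUE(attr(table, "standardized")))
  res <- purrr::pmap(scenarios, function(k, x, y) {
    lattice <- build_hex_lattice(x, y)
    model <- train_batch(table, lattice, config)
    if (restarts > 0) {
      qe_best <- quantization_error(model, table)
      for (r in seq_len(restarts)) {
        cfg_r <- train_config(steps = config$steps,
                              init_radius = config$init_radius,
                              init = "sample",
                              seed = config$seed + 7919L * r,
                              tol = config$tol)
        cand <- train_batch(table, lattice, cfg_r)
        qe_cand <- quantization_error(cand, table)
        if (qe_cand < qe_best) {
          model <- cand
          qe_best <- qe_cand
        }
      }
    }
    labels <- assign_labels(model, table)
    n_nonempty <- length(unique(labels))
    if (n_nonempty < 2) {
      out <- list(model = model, labels = labels, n_nonempty = n_nonempty,
                  mean_si = -1, flagged = TRUE)
    } else {
      si <- silhouette_index(table, labels, sample_size = sample_size,
                             seed = seed)
      out <- list(model = model, labels = labels, n_nonempty = n_nonempty,
                  mean_si = si$mean, flagged = FALSE)
    }
    if (verbose) {
      message(sprintf("scenario %d x %d (k = %d): mean SI = %.4f, %d classes",
                      x, y, k, out$mean_si, out$n_nonempty))
    }
    out
  })
  out <- dplyr::mutate(
    scenarios,
    n_nonempty = purrr::map_int(res, "n_nonempty"),
    mean_si = purrr::map_dbl(res, "mean_si"),
    flagged = purrr::map_lgl(res, "flagged"),
    model = purrr::map(res, "model"),
    labels = purrr::map(res, "labels")
  )
  class(out) <- c("som_scan", class(out))
  out
}

#' Select the best scenario of a scan
#'
#' The scenario with the largest mean silhouette index; ties break toward
#' fewer clusters, then toward the more linear topology (smaller `x`).
#'
#' @param scan A `som_scan` tibble from [run_scan()].
#' @return A list of class `scenario_result`: `k`, `x`, `y`, `model`,
#'   `labels`, `mean_si`, `n_nonempty`.
#' @export
select_best <- function(scan) {
  ok <- !scan$flagged
  if (!any(ok)) stop("every scenario collapsed; nothing to select")
  cand <- scan[ok, ]
  ord <- order(-cand$mean_si, cand$k, cand$x)
  best <- cand[ord[1], ]
  structure(
    list(k = best$k, x = best$x, y = best$y,
         model = best$model[[1]], labels = best$labels[[1]],
         mean_si = best$mean_si, n_nonempty = best$n_nonempty),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %d x %d lattice (k = %d), mean SI = %.4f, %d non-empty classes\n",
    x$x, x$y, x$k, x$mean_si, x$n_nonempty
  ))
  invisible(x)
}
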