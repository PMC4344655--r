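#' Build a hexagonal neuron lattice
#'
#' Neurons sit on an offset hexagonal layout of `x` rows by `y` columns
#' (odd rows shifted half a cell), so interior neurons have exactly six
#' neighbors. A `1 x k` lattice degenerates to a path — the linear topology.
#'
#' @param x,y Lattice dimensions (rows, columns), both `>= 1`.
#' @return A list of class `hex_lattice`: dims `x`, `y`, neuron count `k`,
#'   `positions` (`k x 2` layout coordinates, neurons numbered row-major), and
#'   `edges` (two-column matrix of adjacent neuron pairs, `i < j`).
#' @export
build_hex_lattice <- function(x, y) {
  stopifnot(x >= 1, y >= 1)
  x <- as.integer(x)
  y <- as.integer(y)
  k <- x * y
  id <- function(i, j) (i - 1L) * y + j
  rows <- rep(seq_len(x), each = y)
  cols <- rep(seq_len(y), times = x)
  positions <- cbind(
    px = cols + 0.5 * ((rows - 1L) %% 2L),
    py = (rows - 1L) * sqrt(3) / 2
  )
  edges <- list()
  for (i in seq_len(x)) {
    shifted <- (i - 1L) %% 2L == 1L # odd (0-based) rows shifted +1/2
    for (j in seq_len(y)) {
      nb <- list(c(i, j + 1L))
      if (i < x) {
        nb <- c(nb, list(c(i + 1L, j)),
                if (shifted) list(c(i + 1L, j + 1L)) else list(c(i + 1L, j - 1L)))
      }
      for (p in nb) {
        if (p[1] >= 1 && p[1] <= x && p[2] >= 1 && p[2] <= y) {
          edges[[length(edges) + 1L]] <- c(id(i, j), id(p[1], p[2]))
        }
      }
    }
  }
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  } else {
    matrix(integer(0), 0, 2)
  }
  structure(list(x = x, y = y, k = k, positions = positions, edges = edges),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice> %d x %d (%d neurons, %d edges)\n",
              x$x, x$y, x$k, nrow(x$edges)))
  invisible(x)
}

#' All-pairs link distances on a lattice
#'
#' Entry `(i, j)` is the minimum number of adjacency hops between neurons `i`
#' and `j` — the neighborhood metric used during training.
#'
#' @param lattice A [build_hex_lattice()] lattice.
#' @return `k x k` integer matrix (zero diagonal, symmetric).
#' @export
link_distance_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (lattice$k == 1L) return(matrix(0L, 1, 1))
  g <- igraph::graph_from_edgelist(lattice$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, lattice$k - igraph::vcount(g)))
  d <- igraph::distances(g)
  if (any(is.infinite(d))) stop("lattice is not connected")
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Training configuration for the batch SOM
#'
#' Defaults follow the reference configuration: 1000 training steps and an
#' initial neighborhood radius of 3 link-distance hops. The radius decays
#' linearly from `init_radius` to 1 over the first 90% of the steps (the
#' ordering phase), then is 0 for the final 10% (pure per-neuron mean
#' refinement, so the final partition is a clean Voronoi partition).
#'
#' @param steps Number of batch iterations.
#' @param init_radius Initial link-distance neighborhood radius.
#' @param init Weight initialization: `"pca_plane"` (deterministic, default),
#'   `"sample"` (k distinct data rows drawn under `seed`), or `"random"`
#'   (uniform in the per-column data range under `seed`).
#' @param seed Integer seed (used by random initialization).
#' @param tol Early-stopping threshold on the maximum weight change, applied
#'   once the radius has reached 0.
#' @return A list of class `train_config`.
#' @export
train_config <- function(steps = 1000, init_radius = 3,
                         init = c("pca_plane", "sample", "random"), seed = 1,
                         tol = 1e-9) {
  init <- match.arg(init)
  stopifnot(steps >= 1, init_radius >= 0)
  structure(list(steps = as.integer(steps), init_radius = init_radius,
                 init = init, seed = as.integer(seed), tol = tol),
            class = "train_config")
}

#' Initialize neuron weights
#'
#' `pca_plane` (default, deterministic): neurons are laid out on the plane
#' spanned by the first two principal directions of the data, spanning the
#' mean +/- 2 SD along each direction (first direction only for a linear
#' lattice), then clamped to the per-column data range. `sample`: `k`
#' distinct data rows drawn under `seed` (so every initial weight sits in a
#' populated region). `random`: uniform within each column's data range under
#' `seed`.
#'
#' @param table Standardized feature table (`>= 2` rows).
#' @param lattice A [build_hex_lattice()] lattice.
#' @param method `"pca_plane"`, `"sample"`, or `"random"`.
#' @param seed Integer seed (sample/random methods only).
#' @return `k x 6` weight matrix.
#' @export
init_weights <- function(table, lattice,
                         method = c("pca_plane", "sample", "random"),
                         seed = 1) {
  method <- match.arg(method)
  X <- feature_matrix(table)
  if (nrow(X) < 2) stop("need at least 2 rows to initialize weights")
  k <- lattice$k
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (method %in% c("random", "sample")) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    if (method == "sample") {
      rows <- sample(nrow(X), k, replace = k > nrow(X))
      W <- X[rows, , drop = FALSE]
      dimnames(W) <- NULL
      return(W)
    }
    W <- sapply(seq_len(ncol(X)), function(j) stats::runif(k, lo[j], hi[j]))
    if (k == 1) W <- matrix(W, nrow = 1)
    return(W)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  center <- colMeans(X)
  # map the longer lattice dimension onto the first principal direction
  ri <- (seq_len(k) - 1L) %/% lattice$y + 1L
  ci <- (seq_len(k) - 1L) %% lattice$y + 1L
  axis_coord <- function(pos, n) {
    if (n == 1) rep(0, length(pos)) else (2 * (pos - 1) / (n - 1) - 1)
  }
  if (lattice$y >= lattice$x) {
    t1 <- axis_coord(ci, lattice$y)
    t2 <- axis_coord(ri, lattice$x)
  } else {
    t1 <- axis_coord(ri, lattice$x)
    t2 <- axis_coord(ci, lattice$y)
  }
  sd1 <- pc$sdev[1]
  sd2 <- if (length(pc$sdev) >= 2) pc$sdev[2] else 0
  W <- matrix(center, k, ncol(X), byrow = TRUE) +
    outer(2 * sd1 * t1, pc$rotation[, 1]) +
    (if (sd2 > 0) outer(2 * sd2 * t2, pc$rotation[, 2]) else 0)
  # containment in the data box
  for (j in seq_len(ncol(W))) W[, j] <- pmin(pmax(W[, j], lo[j]), hi[j])
  W
}

# Best-matching unit per row: squared Euclidean distance, ties to the lowest
# neuron index.
bmu_assign <- function(X, W) {
  D <- outer(rowSums(X^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(X)), rowSums(W^2)) - 2 * X %*% t(W)
  max.col(-D, ties.method = "first")
}

#' Train a batch self-organizing map
#'
#' Each step assigns every row to its best-matching unit (BMU, Euclidean
#' distance in feature space, ties to the lowest neuron index), then replaces
#' each neuron's weight by the mean of all rows whose BMU lies within link
#' distance `r(t)` of it (hard-indicator neighborhood). Neurons capturing no
#' rows keep their weight. The radius follows the [train_config()] schedule;
#' during the final radius-0 phase the update is exactly Lloyd's k-means
#' iteration and training stops early once the largest weight change falls
#' below `tol`. The procedure is deterministic given the initialization.
#'
#' @param table Standardized feature table.
#' @param lattice A [build_hex_lattice()] lattice.
#' @param config A [train_config()].
#' @return An object of class `som_model`: `lattice`, `weights` (`k x 6`),
#'   `link_dist`, `config`, `iterations` run.
#' @export
train_batch <- function(table, lattice, config = train_config()) {
  stopifnot(inherits(lattice, "hex_lattice"), inherits(config, "train_config"))
  X <- feature_matrix(table)
  if (nrow(X) == 0) stop("empty feature table")
  if (nrow(X) < lattice$k) {
    warning("fewer rows (", nrow(X), ") than neurons (", lattice$k, ")")
  }
  W <- init_weights(table, lattice, method = config$init, seed = config$seed)
  ld <- link_distance_matrix(lattice)
  # The effective radius is capped one hop below the lattice diameter inside
  # the kernel: a neighborhood spanning the whole lattice carries no
  # topological information and irreversibly averages every neuron to the
  # same weight. Once weights are stationary the state cannot change until
  # the integer part of the radius does, so converged stretches are skipped.
  fit <- som_batch_train_cpp(X, W, ld, config$steps, config$init_radius,
                             config$tol)
  structure(
    list(lattice = lattice, weights = fit$weights, link_dist = ld,
         config = config, iterations = fit$iterations),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d hex lattice, %d features, %d iterations\n",
              x$lattice$x, x$lattice$y, ncol(x$weights), x$iterations))
  invisible(x)
}

#' Quantization error of a trained map
#'
#' Mean Euclidean distance from each row to its best-matching unit's weight
#' vector — the objective the batch updates descend during the radius-0
#' phase, and the standard internal measure for comparing fits of the same
#' lattice.
#'
#' @param model A trained [train_batch()] model.
#' @param table Feature table in the trained column space.
#' @return A single number.
#' @export
quantization_error <- function(model, table) {
  stopifnot(inherits(model, "som_model"))
  X <- feature_matrix(table)
  W <- model$weights
  D <- outer(rowSums(X^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(X)), rowSums(W^2)) - 2 * X %*% t(W)
  mean(sqrt(pmax(apply(D, 1, min), 0)))
}

#' Classify feature rows by best-matching unit
#'
#' @param model A trained [train_batch()] model.
#' @param table Feature table in the same (standardized) column space.
#' @return Integer vector of neuron labels, `1..k`, one per row.
#' @export
assign_labels <- function(model, table) {
  stopifnot(inherits(model, "som_model"))
  X <- feature_matrix(table)
  if (ncol(X) != ncol(model$weights)) {
    stop("feature columns do not match the trained model")
  }
  bmu_assign(X, model$weights)
}

#' Feature-space distances between adjacent neurons
#'
#' The unified-distance (U-matrix) diagnostic: one entry per lattice
#' adjacency edge with the Euclidean distance between the two neurons'
#' weight vectors. Large distances mark class boundaries.
#'
#' @param model A trained [train_batch()] model.
#' @return Tibble with columns `i`, `j` (`i < j`) and `distance`.
#' @export
neighbor_weight_distances <- function(model) {
  stopifnot(inherits(model, "som_model"))
  e <- model$lattice$edges
  d <- sqrt(rowSums((model$weights[e[, 1], , drop = FALSE] -
                       model$weights[e[, 2], , drop = FALSE])^2))
  tibble::tibble(i = e[, 1], j = e[, 2], distance = d)
}

#' Per-variable neuron weight planes
#'
#' Column slices of the weight matrix, one plane per input variable — the
#' component-plane diagnostic showing how each variable shapes each neuron.
#'
#' @param model A trained [train_batch()] model.
#' @return Tibble in long form: `neuron`, `variable` (ordered as
#'   [seascape_variables]), `weight`, plus the neuron's lattice position.
#' @export
input_weight_planes <- function(model) {
  stopifnot(inherits(model, "som_model"))
  W <- model$weights
  vars <- seascape_variables[seq_len(ncol(W))]
  tibble::tibble(
    neuron = rep(seq_len(nrow(W)), times = ncol(W)),
    variable = factor(rep(vars, each = nrow(W)), levels = vars),
    weight = as.vector(W),
    px = rep(model$lattice$positions[, 1], times = ncol(W)),
    py = rep(model$lattice$positions[, 2], times = ncol(W))
  )
}
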