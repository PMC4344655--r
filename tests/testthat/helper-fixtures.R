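# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as literal, brute-force versions of the quantities
# they check, independent of the package's implementation path.

make_geo <- function(n_rows = 10, n_cols = 10,
                     lon_min = 113, lon_max = 135, lat_min = -13, lat_max = 0) {
  grid_geo(lon_min, lon_max, lat_min, lat_max, n_rows, n_cols)
}

make_grid <- function(values, geo = NULL, ...) {
  if (is.null(geo)) geo <- make_geo(nrow(values), ncol(values))
  raster_grid(values, geo, ...)
}

# Feature tibble with the canonical six columns from a plain matrix.
as_feature_tbl <- function(X, standardized = FALSE) {
  colnames(X) <- seascape_variables[seq_len(ncol(X))]
  tbl <- tibble::as_tibble(X)
  attr(tbl, "standardized") <- standardized
  tbl
}

# Stack of constant grids with a simple time axis.
constant_stack <- function(values_list, year = NULL, month = NULL,
                           geo = make_geo(3, 3)) {
  n <- length(values_list)
  if (is.null(month)) month <- (seq_len(n) - 1L) %% 12L + 1L
  if (is.null(year)) year <- 2000L + (seq_len(n) - 1L) %/% 12L
  grids <- lapply(values_list, function(v) {
    raster_grid(matrix(v, geo$n_rows, geo$n_cols), geo, varname = "sst")
  })
  monthly_stack(grids, year, month)
}

# Breadth-first all-pairs hop distances from an edge list (independent of
# igraph, used as the link-distance oracle).
bfs_distances <- function(k, edges) {
  adj <- vector("list", k)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, k, k)
  for (s in seq_len(k)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Literal O(n^2) silhouette: loops over points and clusters.
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  si <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      si[i] <- 0
      next
    }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    si[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  si
}

# One Lloyd k-means iteration (assign to nearest center, ties to the lowest
# index; recompute centers as plain means; empty centers unchanged).
lloyd_step <- function(X, W) {
  D <- outer(rowSums(X^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(X)), rowSums(W^2)) - 2 * X %*% t(W)
  assign <- apply(D, 1, which.min)
  W_new <- W
  for (c in unique(assign)) {
    W_new[c, ] <- unname(colMeans(X[assign == c, , drop = FALSE]))
  }
  dimnames(W_new) <- NULL
  W_new
}

# Separable cubic-convolution oracle: interpolate every row along longitude,
# then every target column along latitude, with 1-D kernel evaluations.
cubic_1d <- function(x_src, v, x_out, a = -0.5) {
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  step <- x_src[2] - x_src[1]
  vapply(x_out, function(x) {
    u <- (x - x_src[1]) / step + 1
    j0 <- floor(u)
    acc <- 0
    for (off in -1:2) {
      j <- j0 + off
      jc <- min(max(j, 1), length(v))
      acc <- acc + kern(u - j) * v[jc]
    }
    acc
  }, numeric(1))
}

bicubic_oracle <- function(values, src_geo, target_geo, a = -0.5) {
  src_lon <- grid_lons(src_geo)
  src_lat <- grid_lats(src_geo)
  out_lon <- grid_lons(target_geo)
  out_lat <- grid_lats(target_geo)
  # rows first (longitude), then columns (latitude); lat axis descends, so
  # interpolate on the descending coordinate directly
  tmp <- t(apply(values, 1, function(row) cubic_1d(src_lon, row, out_lon, a)))
  apply(tmp, 2, function(colv) cubic_1d(-src_lat, colv, -out_lat, a))
}

# 4-connected components of a label matrix (NA = background); returns TRUE
# when every labeled region is a single connected component.
regions_connected <- function(labels) {
  for (lab in sort(unique(labels[!is.na(labels)]))) {
    cells <- which(labels == lab, arr.ind = TRUE)
    if (nrow(cells) == 1) next
    key <- paste(cells[, 1], cells[, 2])
    seen <- logical(nrow(cells))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- rbind(cells[f, ] + c(0, 1), cells[f, ] - c(0, 1),
                    cells[f, ] + c(1, 0), cells[f, ] - c(1, 0))
        hits <- match(paste(nb[, 1], nb[, 2]), key)
        hits <- hits[!is.na(hits)]
        hits <- hits[!seen[hits]]
        seen[hits] <- TRUE
        nxt <- c(nxt, hits)
      }
      frontier <- nxt
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}
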