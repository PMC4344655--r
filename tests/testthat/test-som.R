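test_that("hex lattices have the stated degrees and degenerate to paths", {
  path9 <- build_hex_lattice(1, 9)
  expect_equal(path9$k, 9L)
  ld <- link_distance_matrix(path9)
  expect_equal(ld[1, 9], 8L) # end-to-end hops on the path
  expect_equal(nrow(path9$edges), 8L)

  single <- build_hex_lattice(1, 1)
  expect_equal(nrow(single$edges), 0L)
  expect_equal(link_distance_matrix(single), matrix(0L, 1, 1))

  lat <- build_hex_lattice(4, 5)
  deg <- tabulate(c(lat$edges), nbins = lat$k)
  # interior neurons (rows 2-3, cols 2-4 in row-major numbering) have 6 neighbors
  interior <- c(7, 8, 9, 12, 13, 14)
  expect_true(all(deg[interior] == 6))
  expect_true(all(deg >= 2 & deg <= 6))
  expect_error(build_hex_lattice(0, 3))
})

test_that("link distances equal a breadth-first oracle on all lattices up to 6x6", {
  for (x in 1:6) {
    for (y in x:6) {
      lat <- build_hex_lattice(x, y)
      got <- link_distance_matrix(lat)
      expect_true(all(got == bfs_distances(lat$k, lat$edges)),
                  label = sprintf("lattice %dx%d matches BFS", x, y))
      expect_true(all(got == t(got)))
      expect_true(all(diag(got) == 0))
    }
  }
})

test_that("weight initialization is deterministic, contained, and ordered", {
  set.seed(1)
  X <- matrix(runif(600), 100, 6)
  tbl <- as_feature_tbl(X, standardized = TRUE)
  lat <- build_hex_lattice(3, 4)
  w1 <- init_weights(tbl, lat)
  w2 <- init_weights(tbl, lat)
  expect_identical(w1, w2)
  for (j in 1:6) {
    expect_true(all(w1[, j] >= min(X[, j]) & w1[, j] <= max(X[, j])))
  }
  wr1 <- init_weights(tbl, lat, method = "random", seed = 7)
  wr2 <- init_weights(tbl, lat, method = "random", seed = 7)
  expect_identical(wr1, wr2)
  for (j in 1:6) {
    expect_true(all(wr1[, j] >= min(X[, j]) & wr1[, j] <= max(X[, j])))
  }
  # 1-D data on a 1x3 lattice: weights monotone along the data axis
  line <- as_feature_tbl(cbind(seq(0, 1, length.out = 50),
                               matrix(0.5, 50, 5)), standardized = TRUE)
  w <- init_weights(line, build_hex_lattice(1, 3))
  expect_true(all(diff(w[, 1]) > 0) || all(diff(w[, 1]) < 0))
  expect_error(init_weights(line[1, ], build_hex_lattice(1, 2)), "2 rows")
})

test_that("a 1x1 map converges to the data mean and training is deterministic", {
  set.seed(4)
  X <- matrix(rnorm(300), 50, 6)
  tbl <- as_feature_tbl(X, standardized = TRUE)
  m <- train_batch(tbl, build_hex_lattice(1, 1), train_config(steps = 20))
  expect_equal(as.vector(m$weights), unname(colMeans(X)), tolerance = 1e-12)

  lat <- build_hex_lattice(2, 3)
  m1 <- train_batch(tbl, lat, train_config(steps = 60, seed = 5))
  m2 <- train_batch(tbl, lat, train_config(steps = 60, seed = 5))
  expect_identical(m1$weights, m2$weights)
  expect_error(train_batch(tbl[0, ], lat), "empty")
})

test_that("well-separated blobs are split onto a 1x2 lattice at the blob means", {
  set.seed(42)
  X <- rbind(matrix(rnorm(200, 0, 1), 100, 2), matrix(rnorm(200, 8, 1), 100, 2))
  tbl <- as_feature_tbl(X, standardized = TRUE)
  m <- train_batch(tbl, build_hex_lattice(1, 2), train_config(steps = 200))
  mu <- rbind(colMeans(X[1:100, ]), colMeans(X[101:200, ]))
  # match weights to blob means irrespective of neuron order
  d <- outer(seq_len(2), seq_len(2),
             Vectorize(function(i, j) sqrt(sum((m$weights[i, ] - mu[j, ])^2))))
  expect_lt(min(d[1, ]), 0.01)
  expect_lt(min(d[2, ]), 0.01)
  expect_false(which.min(d[1, ]) == which.min(d[2, ]))
})

test_that("with radius 0 throughout, batch training is Lloyd's k-means", {
  set.seed(9)
  X <- matrix(runif(240), 40, 6)
  tbl <- as_feature_tbl(X, standardized = TRUE)
  lat <- build_hex_lattice(2, 2)
  W0 <- init_weights(tbl, lat)
  # radius-0 schedule: init_radius = 0 caps every step at 0
  steps <- 5
  m <- train_batch(tbl, lat, train_config(steps = steps, init_radius = 0,
                                          tol = 0))
  W <- W0
  for (t in seq_len(steps)) W <- lloyd_step(X, W)
  expect_equal(m$weights, W, tolerance = 1e-12)
})

test_that("a linear map trained on collinear points stays topologically ordered", {
  t_axis <- seq(0, 1, length.out = 90)
  X <- cbind(t_axis, 2 * t_axis, matrix(0.3, 90, 4))
  tbl <- as_feature_tbl(X, standardized = TRUE)
  m <- train_batch(tbl, build_hex_lattice(1, 9), train_config(steps = 300))
  proj <- m$weights[, 1] # position along the line
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
})

test_that("the final partition is a Voronoi partition of the data", {
  set.seed(14)
  X <- matrix(runif(900), 150, 6)
  tbl <- as_feature_tbl(X, standardized = TRUE)
  m <- train_batch(tbl, build_hex_lattice(2, 4), train_config(steps = 100))
  labels <- assign_labels(m, tbl)
  D <- outer(rowSums(X^2), rep(1, nrow(m$weights))) +
    outer(rep(1, nrow(X)), rowSums(m$weights^2)) - 2 * X %*% t(m$weights)
  expect_true(all(abs(D[cbind(seq_len(150), labels)] - apply(D, 1, min)) < 1e-9))
  # brute-force nearest-weight oracle on individual rows
  for (i in sample(150, 25)) {
    d_i <- colSums((t(m$weights) - X[i, ])^2)
    expect_equal(labels[i], which.min(d_i))
  }
  expect_equal(length(labels), nrow(X))
  # a row equal to a neuron weight maps to that neuron
  wtbl <- as_feature_tbl(m$weights[3, , drop = FALSE], standardized = TRUE)
  expect_equal(assign_labels(m, wtbl), 3L)
  expect_error(assign_labels(m, tbl[, 1:4]), "columns")
})

test_that("neighbor distances and weight planes mirror the weight matrix", {
  set.seed(20)
  tbl <- as_feature_tbl(matrix(runif(300), 50, 6), standardized = TRUE)
  lat <- build_hex_lattice(2, 3)
  m <- train_batch(tbl, lat, train_config(steps = 50))
  nd <- neighbor_weight_distances(m)
  expect_equal(nrow(nd), nrow(lat$edges))
  for (r in seq_len(nrow(nd))) {
    expect_equal(nd$distance[r],
                 sqrt(sum((m$weights[nd$i[r], ] - m$weights[nd$j[r], ])^2)))
  }
  m0 <- m
  m0$weights[] <- 0.5
  expect_true(all(neighbor_weight_distances(m0)$distance == 0))
  m2 <- m
  m2$weights[] <- 0
  m2$weights[2, 1] <- 1
  nd2 <- neighbor_weight_distances(m2)
  expect_equal(nd2$distance[nd2$i == 1 & nd2$j == 2], 1)

  planes <- input_weight_planes(m)
  expect_equal(nrow(planes), lat$k * 6)
  expect_equal(levels(planes$variable), seascape_variables)
  W_back <- matrix(planes$weight, nrow = lat$k)
  expect_equal(W_back, m$weights, ignore_attr = TRUE)
  # trained on data spanning [0,1]: final weights are means of points in [0,1]
  expect_true(all(planes$weight >= 0 & planes$weight <= 1))
})
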