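test_that("scenario enumeration lists unordered factor pairs, 43 over 4..25", {
  sc <- enumerate_scenarios(4, 25)
  expect_equal(nrow(sc), 43L)
  expect_true(all(sc$x <= sc$y))
  expect_true(all(sc$x * sc$y == sc$k))
  expect_true(all(sc$k >= 4 & sc$k <= 25))
  expect_false(any(duplicated(sc[, c("x", "y")])))
  expect_equal(sc$k, sort(sc$k))

  sc4 <- enumerate_scenarios(4, 4)
  expect_equal(nrow(sc4), 2L)
  expect_equal(sc4$x, c(1L, 2L))
  expect_equal(sc4$y, c(4L, 2L))
  sc5 <- enumerate_scenarios(5, 5)
  expect_equal(nrow(sc5), 1L)
  expect_equal(c(sc5$x, sc5$y), c(1L, 5L))
  expect_error(enumerate_scenarios(10, 4))
})

test_that("silhouette handles the textbook cases", {
  # two clusters of coincident points, far apart: mean SI = 1
  X <- matrix(c(0, 0, 5, 5), ncol = 1)
  si <- silhouette_index(X, c(1, 1, 2, 2), sample_size = Inf)
  expect_equal(si$mean, 1)

  # hand-computed 1-D instance
  X2 <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  si2 <- silhouette_index(X2, c(1, 1, 2, 2), sample_size = Inf)
  expect_equal(si2$mean, 0.99, tolerance = 1e-5)

  expect_error(silhouette_index(X, c(1, 1, 1, 1), sample_size = Inf),
               "2 non-empty")
  # singleton cluster scores 0
  X3 <- matrix(c(0, 0.2, 7), ncol = 1)
  si3 <- silhouette_index(X3, c(1, 1, 2), sample_size = Inf)
  expect_equal(si3$si[3], 0)
})

test_that("silhouette equals the O(n^2) brute-force oracle on random instances", {
  set.seed(100)
  for (rep in 1:100) {
    n <- sample(10:300, 1)
    k <- sample(2:10, 1)
    p <- sample(1:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    labels <- sample(rep(seq_len(k), length.out = n))
    si <- silhouette_index(X, labels, sample_size = Inf)
    expect_equal(si$si, brute_silhouette(X, labels), tolerance = 1e-12)
    expect_gte(si$mean, -1)
    expect_lte(si$mean, 1)
  }
})

test_that("silhouette agrees with an independent library implementation", {
  skip_if_not_installed("cluster")
  set.seed(55)
  X <- matrix(rnorm(360), 60, 6)
  labels <- sample(rep(1:4, 15))
  ours <- silhouette_index(X, labels, sample_size = Inf)
  ref <- cluster::silhouette(labels, dist(X))
  expect_equal(ours$si, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette is invariant to renaming cluster labels and to row units", {
  set.seed(60)
  X <- matrix(rnorm(200), 50, 4)
  labels <- sample(rep(1:5, 10))
  a <- silhouette_index(X, labels, sample_size = Inf)
  relabel <- c(3L, 5L, 1L, 2L, 4L)[labels]
  b <- silhouette_index(X, relabel, sample_size = Inf)
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  # subsampled evaluation is deterministic under the seed
  s1 <- silhouette_index(X, labels, sample_size = 30, seed = 3)
  s2 <- silhouette_index(X, labels, sample_size = 30, seed = 3)
  expect_identical(s1$mean, s2$mean)
  expect_equal(length(s1$si), 30L)
})

test_that("the scan scores every scenario and is reproducible", {
  set.seed(77)
  X <- rbind(matrix(rnorm(300, 0, 0.2), 50, 6),
             matrix(rnorm(300, 5, 0.2), 50, 6))
  tbl <- as_feature_tbl(X, standardized = TRUE)
  sc <- tibble::tibble(k = c(2L, 4L), x = c(1L, 2L), y = c(2L, 2L))
  scan <- run_scan(tbl, sc, config = train_config(steps = 80),
                   sample_size = Inf)
  expect_equal(nrow(scan), 2L)
  expect_gt(scan$mean_si[scan$k == 2], 0.9) # near-perfect two-blob split
  scan2 <- run_scan(tbl, sc, config = train_config(steps = 80),
                    sample_size = Inf)
  expect_identical(scan$mean_si, scan2$mean_si)
  expect_identical(scan$labels, scan2$labels)
  # tidy/glance accessors
  td <- tidy(scan)
  expect_false("model" %in% names(td))
  expect_equal(glance(scan)$n_scenarios, 2L)
})

test_that("selection maximizes mean SI with ties toward small k then linear", {
  stub <- function(k, x, y, si) {
    tibble::tibble(k = k, x = x, y = y, n_nonempty = k, mean_si = si,
                   flagged = FALSE, model = list(NULL), labels = list(NULL))
  }
  one <- stub(6L, 1L, 6L, 0.5)
  class(one) <- c("som_scan", class(one))
  expect_equal(select_best(one)$k, 6L)

  tied <- dplyr::bind_rows(stub(6L, 2L, 3L, 0.5), stub(6L, 1L, 6L, 0.5),
                           stub(4L, 2L, 2L, 0.4))
  class(tied) <- c("som_scan", class(tied))
  best <- select_best(tied)
  expect_equal(c(best$x, best$y), c(1L, 6L)) # linear topology wins the tie

  smaller_k <- dplyr::bind_rows(stub(8L, 2L, 4L, 0.5), stub(6L, 2L, 3L, 0.5))
  class(smaller_k) <- c("som_scan", class(smaller_k))
  expect_equal(select_best(smaller_k)$k, 6L)

  flagged <- stub(4L, 2L, 2L, -1)
  flagged$flagged <- TRUE
  class(flagged) <- c("som_scan", class(flagged))
  expect_error(select_best(flagged), "collapsed")
})

test_that("a collapsed scenario is flagged with mean SI -1, not an error", {
  # all rows identical: every neuron weight coincides, one non-empty class
  X <- matrix(0.5, 30, 6)
  tbl <- as_feature_tbl(X, standardized = TRUE)
  sc <- tibble::tibble(k = 4L, x = 2L, y = 2L)
  scan <- run_scan(tbl, sc, config = train_config(steps = 20),
                   sample_size = Inf)
  expect_true(scan$flagged[1])
  expect_equal(scan$mean_si[1], -1)
  expect_equal(scan$n_nonempty[1], 1L)
})
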