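make_raw_table <- function(X, geo = NULL) {
  n <- nrow(X)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  if (is.null(geo)) geo <- make_geo(nr, nc)
  tbl <- as_feature_tbl(X)
  idx <- seq_len(n)
  tbl <- dplyr::mutate(tbl,
                       row = (idx - 1L) %/% nc + 1L,
                       col = (idx - 1L) %% nc + 1L,
                       .before = 1)
  attr(tbl, "geo") <- geo
  tbl
}

test_that("class summaries compute population statistics and area shares", {
  X <- matrix(rep(c(1, 3, 10), 6), 3, 6)
  tbl <- make_raw_table(X)
  s <- class_summary(tbl, c(1L, 1L, 2L))
  expect_equal(s$avg_sst_mean, c(2, 10))
  expect_equal(s$avg_sst_sd, c(1, 0)) # population SD
  expect_equal(s$pct_area, c(200 / 3, 100 / 3))
  expect_equal(sum(s$pct_area), 100)

  # sample-SD option
  s2 <- class_summary(tbl, c(1L, 1L, 2L), sd_type = "sample")
  expect_equal(s2$avg_sst_sd[1], sd(c(1, 3)))

  # single class covering everything
  s3 <- class_summary(tbl, rep(1L, 3))
  expect_equal(s3$pct_area, 100)
  expect_equal(s3$avg_sst_mean, mean(X[, 1]))
  expect_equal(s3$avg_sst_sd, sqrt(mean((X[, 1] - mean(X[, 1]))^2)))
})

test_that("classes outside the interest area score 0% but are still profiled", {
  set.seed(8)
  X <- matrix(rnorm(120, 20), 20, 6)
  geo <- make_geo(4, 5)
  tbl <- make_raw_table(X, geo)
  labels <- rep(c(1L, 2L), each = 10)
  interest <- matrix(FALSE, 4, 5)
  interest[cbind(tbl$row[1:10], tbl$col[1:10])] <- TRUE # class 1 only
  s <- class_summary(tbl, labels, interest_mask = interest)
  expect_equal(s$pct_area, c(100, 0))
  expect_equal(s$avg_sst_mean[2], mean(X[11:20, 1])) # profiled from all pixels
  expect_error(class_summary(tbl, labels, interest_mask = matrix(FALSE, 4, 5)),
               "no classified pixels")
  # percentages are permutation-invariant up to reordering
  relabeled <- c(2L, 1L)[labels]
  s_perm <- class_summary(tbl, relabeled, interest_mask = interest)
  expect_equal(sort(s_perm$pct_area), sort(s$pct_area))
})

test_that("class means stay inside each variable's global range", {
  set.seed(12)
  X <- matrix(rnorm(600, 25, 3), 100, 6)
  tbl <- make_raw_table(X, make_geo(10, 10))
  labels <- sample(1:5, 100, replace = TRUE)
  s <- class_summary(tbl, labels)
  for (v in seascape_variables) {
    m <- s[[paste0(v, "_mean")]]
    expect_true(all(m >= min(tbl[[v]]) & m <= max(tbl[[v]])))
    expect_true(all(s[[paste0(v, "_sd")]] >= 0))
  }
  # ranges over all classes equal the componentwise min/max of the means
  r <- summary_ranges(s)
  for (v in seascape_variables) {
    m <- s[[paste0(v, "_mean")]]
    expect_equal(r$min[r$variable == v], min(m))
    expect_equal(r$max[r$variable == v], max(m))
    expect_equal(r$range[r$variable == v], max(m) - min(m))
  }
  expect_equal(summary_ranges(s, classes = 2)$range, rep(0, 6))
  expect_error(summary_ranges(s, classes = 99), "unknown class")
})

test_that("the shipped reference summary reproduces the printed range arithmetic", {
  ref <- sbs_reference_summary()
  expect_equal(nrow(ref), 9L)
  expect_equal(sum(ref$pct_area), 100, tolerance = 1e-9)

  r_all <- summary_ranges(ref)
  expect_equal(r_all$range[r_all$variable == "avg_sst"], 2.45, tolerance = 1e-9)
  expect_equal(r_all$range[r_all$variable == "max_sst"], 1.71, tolerance = 1e-9)
  expect_equal(r_all$range[r_all$variable == "min_sst"], 3.64, tolerance = 1e-9)
  expect_equal(r_all$max[r_all$variable == "chla"], 1.54)
  expect_equal(r_all$max[r_all$variable == "currents"], 0.33)

  major <- c(2, 4, 5, 6)
  r_major <- summary_ranges(ref, classes = major)
  expect_equal(r_major$range[r_major$variable == "avg_sst"], 0.61,
               tolerance = 1e-9)
  expect_equal(r_major$range[r_major$variable == "max_sst"], 0.69,
               tolerance = 1e-9)
  expect_equal(r_major$range[r_major$variable == "min_sst"], 1.42,
               tolerance = 1e-9)
  expect_equal(r_major$max[r_major$variable == "chla"], 0.36)
  expect_gte(sum(ref$pct_area[ref$class %in% major]), 93)
  expect_equal(sum(ref$pct_area[ref$class %in% major]), 93.3, tolerance = 1e-9)

  # long-form tidier
  td <- tidy(ref)
  expect_equal(nrow(td), 9L * 6L)
  expect_equal(td$mean[td$class == 5 & td$variable == "currents"], 0.33)
})

test_that("class maps export as integer rasters and round-trip exactly", {
  set.seed(33)
  X <- matrix(rnorm(90), 15, 6)
  geo <- make_geo(5, 4)
  tbl <- make_raw_table(X, geo)
  labels <- sample(1:3, 15, replace = TRUE)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "classes.asc")
  export_class_map(labels, tbl, p, geo = geo)
  back <- read_grid(p)
  expect_identical(as.integer(back$values[cbind(tbl$row, tbl$col)]), labels)
  expect_true(all(back$values[back$mask] %in% 1:3))
  # nodata count = cells not classified
  expect_equal(sum(!back$mask), geo$n_rows * geo$n_cols - nrow(tbl))
})
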