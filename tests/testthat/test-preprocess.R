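test_that("bicubic resampling is exact on constant and linear fields", {
  src_geo <- grid_geo(0, 12, 0, 12, n_rows = 12, n_cols = 12)
  tgt_geo <- grid_geo(2, 10, 2, 10, n_rows = 24, n_cols = 24)
  const <- raster_grid(matrix(3.5, 12, 12), src_geo)
  out <- resample_bicubic(const, tgt_geo)
  expect_equal(out$values, matrix(3.5, 24, 24), tolerance = 1e-12)

  lons <- grid_lons(src_geo); lats <- grid_lats(src_geo)
  ramp <- outer(lats, lons, function(la, lo) 2 + 0.3 * lo - 0.7 * la)
  rg <- raster_grid(ramp, src_geo)
  out2 <- resample_bicubic(rg, tgt_geo)
  want <- outer(grid_lats(tgt_geo), grid_lons(tgt_geo),
                function(la, lo) 2 + 0.3 * lo - 0.7 * la)
  expect_equal(out2$values, want, tolerance = 1e-9)
})

test_that("bicubic resampling matches the separable 1-D kernel oracle", {
  set.seed(17)
  src_geo <- grid_geo(0, 10, 0, 10, n_rows = 10, n_cols = 10)
  tgt_geo <- grid_geo(1, 9, 1, 9, n_rows = 27, n_cols = 27)
  v <- matrix(rnorm(100), 10, 10)
  g <- raster_grid(v, src_geo)
  got <- resample_bicubic(g, tgt_geo)$values
  want <- bicubic_oracle(v, src_geo, tgt_geo)
  expect_equal(got, want, tolerance = 1e-9)
  # commutes with adding a constant
  got_shift <- resample_bicubic(raster_grid(v + 4, src_geo), tgt_geo)$values
  expect_equal(got_shift, got + 4, tolerance = 1e-9)
  expect_error(resample_bicubic(g, grid_geo(-5, 5, 0, 10, 10, 10)),
               "not covered")
})

test_that("coastal cells are pre-filled from the nearest valid value", {
  src_geo <- grid_geo(0, 8, 0, 8, n_rows = 8, n_cols = 8)
  v <- matrix(2, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  mask[1:4, 1:4] <- FALSE # a land block
  v[!mask] <- NA
  g <- raster_grid(v, src_geo, mask = mask)
  tgt_geo <- grid_geo(1, 7, 1, 7, n_rows = 12, n_cols = 12)
  out <- resample_bicubic(g, tgt_geo)
  # with a constant sea field, nearest-fill keeps the field constant, so no
  # nodata bleed can distort coastal values
  expect_equal(out$values, matrix(2, 12, 12), tolerance = 1e-12)
})

test_that("collinearity screen flags duplicated and negated columns", {
  set.seed(23)
  X <- matrix(rnorm(400), 100, 4)
  X <- cbind(X, X[, 1], -X[, 2])
  tbl <- as_feature_tbl(X)
  expect_warning(res <- assess_collinearity(tbl), "collinear")
  r_dup <- res$r[res$var1 == "avg_sst" & res$var2 == "currents"]
  r_neg <- res$r[res$var1 == "max_sst" & res$var2 == "salinity"]
  expect_equal(r_dup, 1)
  expect_equal(r_neg, -1)
  expect_true(all(res$flagged[abs(res$r) >= 0.85]))
  # independent noise: nothing flagged, all |r| small
  Xi <- matrix(rnorm(60000), 10000, 6)
  resi <- assess_collinearity(as_feature_tbl(Xi))
  expect_true(all(abs(resi$r) < 0.05))
  expect_false(any(resi$flagged))
  Xz <- X; Xz[, 3] <- 1
  expect_error(assess_collinearity(as_feature_tbl(Xz)), "zero-variance")
})

test_that("range standardization attains exact 0/1 extremes and inverts", {
  tbl <- as_feature_tbl(cbind(c(2, 4, 6), c(0, 0.5, 1), c(1, 2, 3),
                              c(5, 6, 7), c(0.1, 0.2, 0.3), c(30, 33, 36)))
  std <- range_standardize(tbl)
  expect_equal(std$avg_sst, c(0, 0.5, 1))
  expect_equal(std$max_sst, c(0, 0.5, 1)) # already spanning [0,1]: unchanged
  for (v in seascape_variables) {
    expect_identical(min(std[[v]]), 0)
    expect_identical(max(std[[v]]), 1)
  }
  back <- range_unstandardize(std)
  for (v in seascape_variables) {
    expect_equal(back[[v]], tbl[[v]], tolerance = 1e-12)
  }
  const <- tbl; const$chla <- rep(2, 3)
  expect_error(range_standardize(const), "constant")

  set.seed(2)
  big <- as_feature_tbl(matrix(rnorm(600, 20, 4), 100, 6))
  stdb <- range_standardize(big)
  for (v in seascape_variables) {
    expect_identical(range(stdb[[v]]), c(0, 1))
  }
})

test_that("feature table assembly keeps only fully valid sea pixels, row-major", {
  geo <- make_geo(2, 2)
  grids <- setNames(lapply(1:6, function(i) {
    make_grid(matrix(as.numeric(i * 1:4), 2, 2, byrow = TRUE), geo)
  }), seascape_variables)
  tbl <- build_feature_table(grids, matrix(TRUE, 2, 2))
  expect_equal(nrow(tbl), 4L)
  expect_equal(tbl$row, c(1L, 1L, 2L, 2L)) # row-major scan
  expect_equal(tbl$col, c(1L, 2L, 1L, 2L))
  expect_equal(tbl$avg_sst, c(1, 2, 3, 4))

  # one invalid pixel in one variable drops that row everywhere
  g2 <- grids
  v <- g2$chla$values; v[2, 1] <- NA
  g2$chla <- raster_grid(v, geo)
  tbl2 <- build_feature_table(g2, matrix(TRUE, 2, 2))
  expect_equal(nrow(tbl2), 3L)
  expect_false(any(tbl2$row == 2 & tbl2$col == 1))

  # row count equals the mask conjunction count on a random fixture
  set.seed(31)
  geo3 <- make_geo(15, 12)
  g3 <- setNames(lapply(1:6, function(i) {
    m <- matrix(runif(180) > 0.1, 15, 12)
    v <- matrix(rnorm(180), 15, 12); v[!m] <- NA
    raster_grid(v, geo3, mask = m)
  }), seascape_variables)
  sea <- matrix(runif(180) > 0.2, 15, 12)
  keep_n <- sum(sea & Reduce(`&`, lapply(g3, function(g) g$mask)))
  tbl3 <- build_feature_table(g3, sea)
  expect_equal(nrow(tbl3), keep_n)
  expect_error(build_feature_table(g3, matrix(FALSE, 15, 12)), "no usable")

  # scatter-back is the identity on valid cells
  back <- feature_to_grid(tbl3, "salinity", geo3)
  expect_equal(back$values[cbind(tbl3$row, tbl3$col)], tbl3$salinity)
  expect_equal(sum(back$mask), nrow(tbl3))
})
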