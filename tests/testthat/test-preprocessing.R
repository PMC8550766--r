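# Maximum-value compositing, Savitzky-Golay smoothing, NIRv, masking and
# grid aggregation.

test_that("maximum compositing takes the pairwise max and skips missing", {
  s <- composite_series(2000, seq(1, by = 8, length.out = 4),
                        c(0.3, 0.7, NA, 0.4), 8)
  out <- composite_max(s)
  expect_equal(out$values, c(0.7, 0.4))
  expect_equal(out$doy, c(1, 17))
  expect_equal(out$interval, 16)
  # both constituents missing -> missing
  s2 <- composite_series(2000, c(1, 9), c(NA, NA), 8)
  expect_true(is.na(composite_max(s2)$values))
})

test_that("maximum compositing matches a brute-force pairwise max", {
  set.seed(1)
  for (rep in 1:5) {
    v <- runif(46)
    v[sample(46, 6)] <- NA
    s <- composite_series(2000, seq(1, by = 8, length.out = 46), v, 8)
    out <- composite_max(s)
    brute <- vapply(seq_len(23), function(i) {
      pair <- v[c(2 * i - 1, 2 * i)]
      if (all(is.na(pair))) NA_real_ else max(pair, na.rm = TRUE)
    }, numeric(1))
    expect_identical(out$values, brute)
  }
})

test_that("compositing is idempotent on 16-day input", {
  s <- composite_series(2000, seq(1, by = 16, length.out = 23), runif(23), 16)
  expect_identical(composite_max(s), s)
  expect_error(composite_max(composite_series(2000, 1:5, runif(5), 1)),
               "8-day")
})

test_that("cube compositing equals the per-series operation", {
  set.seed(2)
  vals <- array(runif(2 * 46 * 3 * 3), c(2, 46, 3, 3))
  cube <- signal_cube(vals, 2000:2001, seq(1, by = 8, length.out = 46), 8)
  out <- composite_max_cube(cube)
  for (y in 1:2) for (r in 1:3) for (cl in 1:3) {
    ser <- composite_max(cube_series(cube, y, r, cl))
    expect_equal(out$values[y, , r, cl], ser$values)
  }
})

test_that("Savitzky-Golay reproduces polynomials up to the fit order", {
  x <- seq(1, by = 16, length.out = 23)
  y <- 2 - 0.03 * x + 0.0001 * x^2
  s <- composite_series(2000, x, y, 16)
  out <- smooth_savitzky_golay(s, window = 7, polyorder = 3)
  expect_lt(max(abs(out$values - y)), 1e-9)
  expect_identical(out$doy, s$doy)        # timestamps preserved
  # constant series unchanged
  cs <- composite_series(2000, x, rep(0.4, 23), 16)
  expect_lt(max(abs(smooth_savitzky_golay(cs)$values - 0.4)), 1e-12)
})

test_that("smoothing agrees with signal::sgolayfilt and reduces noise", {
  p <- cycle_params(noise_sd = 0.05)
  rmse_raw <- rmse_smooth <- numeric(100)
  for (s in 1:100) {
    cyc <- generate_annual_cycle(p, 2000, 16, s)
    sm <- smooth_savitzky_golay(cyc$series, 7, 3)
    expect_equal(sm$values, signal::sgolayfilt(cyc$series$values, 3, 7),
                 tolerance = 1e-12)
    clean <- double_logistic(rep_day(cyc$series$doy, 16), p)
    rmse_raw[s] <- sqrt(mean((cyc$series$values - clean)^2))
    rmse_smooth[s] <- sqrt(mean((sm$values - clean)^2))
  }
  expect_lt(mean(rmse_smooth), mean(rmse_raw))
})

test_that("smoothing flags unusable series instead of failing", {
  short <- composite_series(2000, c(1, 17, 33), runif(3), 16)
  expect_false(attr(smooth_savitzky_golay(short), "valid"))
  gappy <- composite_series(2000, seq(1, by = 16, length.out = 23),
                            c(runif(10), rep(NA, 13)), 16)
  expect_false(attr(smooth_savitzky_golay(gappy), "valid"))
  # moderate gaps are interpolated and smoothed
  v <- double_logistic(seq(8.5, by = 16, length.out = 23), cycle_params())
  v[c(4, 12)] <- NA
  ok <- smooth_savitzky_golay(
    composite_series(2000, seq(1, by = 16, length.out = 23), v, 16))
  expect_true(attr(ok, "valid"))
  expect_false(anyNA(ok$values))
})

test_that("cube smoothing equals the per-series smoother", {
  sc <- generate_scene(3, 3, 2000:2001, seed = 9)
  cube <- sc$signal$SIF
  out <- smooth_cube(cube, 7, 3)
  for (y in 1:2) for (r in 1:3) for (cl in 1:3) {
    ser <- smooth_savitzky_golay(cube_series(cube, y, r, cl), 7, 3)
    expect_equal(out$values[y, , r, cl], ser$values, tolerance = 1e-12)
  }
})

test_that("NIRv is the elementwise NDVI x NIR product", {
  doy <- seq(1, by = 16, length.out = 23)
  set.seed(3)
  ndvi <- composite_series(2000, doy, runif(23, 0, 1), 16, "NDVI")
  nir <- composite_series(2000, doy, runif(23, 0, 0.5), 16, "NIR")
  out <- compute_nirv(ndvi, nir)
  expect_identical(out$values, ndvi$values * nir$values)
  expect_equal(out$variable, "NIRv")
  # single-value contracts and missing propagation
  a <- composite_series(2000, 1, 0.8, 16, "NDVI")
  b <- composite_series(2000, 1, 0.3, 16, "NIR")
  expect_equal(compute_nirv(a, b)$values, 0.24)
  a2 <- composite_series(2000, c(1, 17), c(0, NA), 16, "NDVI")
  b2 <- composite_series(2000, c(1, 17), c(0.3, 0.4), 16, "NIR")
  expect_equal(compute_nirv(a2, b2)$values, c(0, NA))
  # misalignment is a contract error
  c2 <- composite_series(2000, c(9, 25), c(0.3, 0.4), 16, "NIR")
  expect_error(compute_nirv(a2, c2), "aligned")
})

test_that("low-vegetation mask applies a strict < threshold on mean EVI", {
  vals <- array(NA_real_, c(2, 3, 2, 2))
  vals[, , 1, 1] <- 0.05
  vals[, , 1, 2] <- 0.30
  vals[, , 2, 1] <- 0.08          # boundary: retained
  vals[, , 2, 2] <- NA            # all-missing: excluded, warns
  cube <- signal_cube(vals, 2000:2001, c(1, 17, 33), 16, "EVI")
  expect_warning(keep <- mask_low_vegetation(cube, 0.08), "all-missing")
  expect_identical(keep, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
})

test_that("grid aggregation takes missing-skipped block means", {
  vals <- array(NA_real_, c(1, 1, 2, 2))
  vals[1, 1, , ] <- matrix(1:4, 2, 2)
  cube <- signal_cube(vals, 2000, 1, 16, resolution = 0.05)
  out <- aggregate_to_grid(cube, 0.1)
  expect_equal(out$values[1, 1, 1, 1], 2.5)
  vals[1, 1, , ] <- matrix(c(1, NA, NA, NA), 2, 2)
  cube <- signal_cube(vals, 2000, 1, 16, resolution = 0.05)
  expect_equal(aggregate_to_grid(cube, 0.1)$values[1, 1, 1, 1], 1)
  expect_error(aggregate_to_grid(cube, 0.07), "integer multiple")
})

test_that("aggregation matches a brute-force block-mean loop", {
  set.seed(4)
  vals <- array(runif(2 * 3 * 10 * 10), c(2, 3, 10, 10))
  vals[sample(length(vals), 50)] <- NA
  cube <- signal_cube(vals, 2000:2001, c(1, 17, 33), 16, resolution = 0.05)
  out <- aggregate_to_grid(cube, 0.1)
  for (y in 1:2) for (j in 1:3) for (r in 1:5) for (cl in 1:5) {
    block <- vals[y, j, (2 * r - 1):(2 * r), (2 * cl - 1):(2 * cl)]
    expected <- if (all(is.na(block))) NA_real_ else mean(block, na.rm = TRUE)
    expect_equal(out$values[y, j, r, cl], expected)
  }
})
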