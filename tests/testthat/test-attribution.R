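# Preseason aggregation, partial correlation, optimal-window search and
# standardized sensitivities.

test_that("preseason aggregation averages temperatures and sums precipitation", {
  ny <- 3
  dims <- c(ny, 365, 1, 1)
  clim <- climate_cube(array(20, dims), array(10, dims), array(1, dims),
                       2000:2002)
  # constant Tmin: any window returns the constant
  for (k in 1:5)
    expect_equal(unname(preseason_aggregate(clim, 1, 1, 10, k, "Tmin")),
                 rep(10, ny))
  # 1 mm/day over Jul-Sep (92 days) -> 92 mm
  expect_equal(unname(preseason_aggregate(clim, 1, 1, 10, 3, "Pre")),
               rep(92, ny))
})

test_that("preseason aggregation matches a brute-force day loop", {
  sc <- generate_scene(2, 2, 2000:2004, seed = 16)
  clim <- sc$climate
  for (f in c("Tmin", "Tmax", "Pre")) for (k in c(1, 3, 5)) {
    got <- preseason_aggregate(clim, 2, 1, 10, k, f)
    months <- 10 - (k:1)
    days <- unlist(lapply(months, month_days))
    arr <- switch(f, Tmin = clim$tmin, Tmax = clim$tmax, Pre = clim$pre)
    brute <- vapply(1:5, function(iy) {
      v <- arr[iy, days, 2, 1]
      if (f == "Pre") sum(v) else mean(v)
    }, numeric(1))
    expect_equal(unname(got), brute, tolerance = 1e-12)
  }
})

test_that("windows crossing into the previous year drop the first year", {
  sc <- generate_scene(1, 1, 2000:2011, seed = 17)
  w <- preseason_aggregate(sc$climate, 1, 1, 2, 4, "Tmin")  # Oct-Jan window
  expect_true(is.na(w[1]))
  expect_true(all(is.finite(w[-1])))
  # brute-force check for the second year: Oct-Dec of year 1 + Jan of year 2
  days_prev <- unlist(lapply(10:12, month_days))
  expected <- mean(c(sc$climate$tmin[1, days_prev, 1, 1],
                     sc$climate$tmin[2, month_days(1), 1, 1]))
  expect_equal(unname(w[2]), expected, tolerance = 1e-12)
})

test_that("the fast monthly path equals the daily aggregator", {
  sc <- generate_scene(2, 2, 2000:2003, seed = 18)
  monthly <- phenoseason:::monthly_climate(sc$climate)
  for (f in c("Tmin", "Tmax", "Pre")) for (k in 1:5) {
    a <- phenoseason:::window_from_monthly(monthly, f, 1, 2, 10, k)
    b <- preseason_aggregate(sc$climate, 1, 2, 10, k, f)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("partial correlation honours exact and degenerate contracts", {
  set.seed(11)
  n <- 15
  z1 <- rnorm(n); z2 <- rnorm(n); x <- rnorm(n)
  pc <- partial_correlation(x, x, z1, z2)
  expect_equal(pc$partial_r, 1, tolerance = 1e-12)
  # zero variance and collinear controls are flagged, not thrown
  expect_false(partial_correlation(rep(1, n), x, z1, z2)$valid)
  expect_false(partial_correlation(x, x, z1, z1 * 2 + 1e-9)$valid)
  expect_false(partial_correlation(x[1:5], x[1:5], z1[1:5], z2[1:5])$valid)
})

test_that("residual-method partial r equals the precision-matrix formula", {
  set.seed(12)
  for (i in 1:200) {
    n <- 15
    y <- rnorm(n); x <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
    pc <- partial_correlation(y, x, z1, z2, n_min = 10)
    P <- solve(cor(cbind(y, x, z1, z2)))
    expect_equal(pc$partial_r, -P[1, 2] / sqrt(P[1, 1] * P[2, 2]),
                 tolerance = 1e-10)
    # symmetry in the two controls
    pc2 <- partial_correlation(y, x, z2, z1, n_min = 10)
    expect_equal(pc$partial_r, pc2$partial_r, tolerance = 1e-12)
  }
})

test_that("partial correlation is invariant to affine transforms", {
  set.seed(13)
  n <- 19
  y <- rnorm(n); x <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  a <- partial_correlation(y, x, z1, z2)
  # positive scalings of y and x, arbitrary affine controls: r unchanged
  b <- partial_correlation(3 * y - 7, 0.2 * x + 5, -2 * z1 + 1, 10 * z2)
  expect_equal(a$partial_r, b$partial_r, tolerance = 1e-10)
  # a negative scaling of x flips only the sign
  d <- partial_correlation(y, -4 * x + 2, z1, z2)
  expect_equal(a$partial_r, -d$partial_r, tolerance = 1e-10)
})

test_that("the null is calibrated: y built from a control alone", {
  set.seed(14)
  rs <- vapply(1:1000, function(i) {
    n <- 19
    z1 <- rnorm(n); z2 <- rnorm(n); x <- rnorm(n)
    y <- z1 + rnorm(n)
    partial_correlation(y, x, z1, z2)$partial_r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.3)
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("optimal window search matches an exhaustive loop and tie rule", {
  sc <- small_coupled_scene(3, 3, seed = 19)
  e <- suppressMessages(
    extract_egs_cube(smooth_cube(sc$signal$SIF), "dynamic_threshold"))
  monthly <- phenoseason:::monthly_climate(sc$climate)
  y <- e$egs[, 2, 2]
  windows <- lapply(c("Tmin", "Tmax", "Pre"), function(f)
    vapply(1:5, function(k)
      phenoseason:::window_from_monthly(monthly, f, 2, 2, 10, k),
      numeric(length(y))))
  names(windows) <- c("Tmin", "Tmax", "Pre")
  got <- optimal_preseason(y, windows = windows, factor = "Tmin")
  brute <- vapply(1:5, function(k)
    partial_correlation(y, windows$Tmin[, k], windows$Tmax[, k],
                        windows$Pre[, k])$partial_r, numeric(1))
  expect_equal(got$optimal_k, which.max(abs(brute)))
  expect_equal(got$partial_r, brute[got$optimal_k], tolerance = 1e-12)
  # degenerate climate with identical correlations at all k -> k = 1
  nw <- lapply(windows, function(w) matrix(w[, 1], nrow(w), 5))
  tie <- optimal_preseason(y, windows = nw, factor = "Tmin")
  expect_equal(tie$optimal_k, 1L)
})

test_that("sensitivity regression recovers exact and planted coefficients", {
  set.seed(15)
  n <- 19
  tmin <- rnorm(n); tmax <- rnorm(n); pre <- rnorm(n)
  y <- 2 * phenoseason:::zscore(tmin)
  sr <- sensitivity_regression(y, tmin, tmax, pre)
  expect_equal(unname(sr$coefficients), c(2, 0, 0), tolerance = 1e-10)
  expect_equal(sr$r_squared, 1, tolerance = 1e-10)
  # closed-form normal-equations oracle
  y2 <- 280 + 2 * tmin - tmax + 0.5 * pre + rnorm(n, 0, 1)
  sr2 <- sensitivity_regression(y2, tmin, tmax, pre)
  X <- cbind(1, scale(tmin), scale(tmax), scale(pre))
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(sr2$coefficients), unname(beta[2:4]),
               tolerance = 1e-10)
  # singular design flagged
  expect_false(sensitivity_regression(y2, tmin, tmin, pre)$valid)
})

test_that("planted sensitivities are recovered in the median over pixels", {
  set.seed(16)
  n <- 19
  coefs <- t(vapply(1:500, function(i) {
    tmin <- rnorm(n); tmax <- rnorm(n); pre <- rnorm(n)
    y <- 290 + 2 * phenoseason:::zscore(tmin) - phenoseason:::zscore(tmax) +
      0.5 * phenoseason:::zscore(pre) + rnorm(n, 0, 3)
    sensitivity_regression(y, tmin, tmax, pre)$coefficients
  }, numeric(3)))
  med <- apply(coefs, 2, median)
  expect_lt(abs(med[1] - 2), 0.5)
  expect_lt(abs(med[2] + 1), 0.5)
  expect_lt(abs(med[3] - 0.5), 0.5)
})

test_that("attribution map recovers planted signs and its census counts", {
  sc <- small_coupled_scene(10, 10, seed = 20)
  e <- suppressMessages(
    extract_egs_cube(smooth_cube(sc$signal$SIF), "dynamic_threshold"))
  am <- attribution_map(e, sc$climate)
  expect_gt(am$census$Tmin$fraction_positive, 0.7)
  expect_gt(am$census$Tmax$fraction_negative, 0.5)
  # census equals a brute-force count
  r <- am$partial_r$Tmin
  p <- am$p_value$Tmin
  ok <- is.finite(r)
  expect_equal(am$census$Tmin$fraction_positive, sum(r[ok] > 0) / sum(ok))
  expect_equal(am$census$Tmin$fraction_positive_significant,
               sum(r[ok] > 0 & p[ok] < 0.05) / sum(ok))
  expect_true(all(abs(r[ok]) <= 1))
  expect_true(all(am$p_value$Tmin[ok] >= 0 & am$p_value$Tmin[ok] <= 1))
})

test_that("a null scene gives sign fractions near one half", {
  sc <- generate_scene(12, 12, 2000:2018,
                       coupling = coupling_spec(egs_noise_sd = 3), seed = 21)
  e <- suppressMessages(
    extract_egs_cube(smooth_cube(sc$signal$SIF), "dynamic_threshold"))
  am <- attribution_map(e, sc$climate)
  for (f in c("Tmin", "Tmax", "Pre")) {
    expect_lt(abs(am$census[[f]]$fraction_positive - 0.5), 0.2)
  }
})

test_that("biome attribution uses class means and recovers opposite signs", {
  lc <- matrix(rep(c("EBF", "grassland"), each = 50), 10, 10)
  coup <- list(EBF = coupling_spec(beta_tmin = 3, true_window_months = 3,
                                   egs_noise_sd = 1),
               grassland = coupling_spec(beta_tmin = -3,
                                         true_window_months = 3,
                                         egs_noise_sd = 1))
  sc <- generate_scene(10, 10, 2000:2018, coupling = coup, landcover = lc,
                       seed = 22)
  e <- suppressMessages(
    extract_egs_cube(smooth_cube(sc$signal$SIF), "dynamic_threshold"))
  ba <- biome_attribution(e, sc$climate, lc)
  r_ebf <- ba$partial_r[ba$class == "EBF" & ba$factor == "Tmin"]
  r_gra <- ba$partial_r[ba$class == "grassland" & ba$factor == "Tmin"]
  expect_gt(r_ebf, 0)
  expect_lt(r_gra, 0)
  # single-class scene: class result equals the spatial-mean pixel series
  sc1 <- small_coupled_scene(4, 4, seed = 23)
  e1 <- suppressMessages(
    extract_egs_cube(smooth_cube(sc1$signal$SIF), "dynamic_threshold"))
  lc1 <- matrix("shrub", 4, 4)
  ba1 <- biome_attribution(e1, sc1$climate, lc1)
  ym <- vapply(seq_along(e1$years), function(y) mean(e1$egs[y, , ]),
               numeric(1))
  monthly <- phenoseason:::monthly_climate(sc1$climate)
  am <- month_of_doy(mean(ym))
  idx <- which(lc1 == "shrub")
  rc <- arrayInd(idx, dim(lc1))
  windows <- lapply(c("Tmin", "Tmax", "Pre"), function(f) {
    acc <- matrix(0, length(ym), 5)
    for (i in seq_len(nrow(rc)))
      acc <- acc + vapply(1:5, function(k)
        phenoseason:::window_from_monthly(monthly, f, rc[i, 1], rc[i, 2],
                                          am, k), numeric(length(ym)))
    acc / nrow(rc)
  })
  names(windows) <- c("Tmin", "Tmax", "Pre")
  opt <- optimal_preseason(ym, windows = windows, factor = "Tmin")
  expect_equal(ba1$partial_r[ba1$class == "shrub" & ba1$factor == "Tmin"],
               opt$partial_r, tolerance = 1e-12)
})
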