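# Preseason climate attribution: window aggregation over 1-5 whole calendar
# months before the EGS month, optimal-window partial-correlation search and
# standardized multiple-regression sensitivities.

CLIMATE_FACTORS <- c("Tmin", "Tmax", "Pre")

#' Aggregate daily climate over a preseason window for one pixel
#'
#' The window spans `k` whole calendar months ending at the month before
#' `anchor_month`; temperatures are averaged over its days, precipitation
#' is summed, separately per year. Months before January are taken from the
#' previous calendar year; years whose window would extend before the first
#' available climate day are dropped (`NA`).
#'
#' @param climate a [climate_cube()]
#' @param row,col pixel indices
#' @param anchor_month calendar month (1..12) containing the pixel's
#'   climatological EGS
#' @param k window length in months (1..5)
#' @param factor `"Tmin"`, `"Tmax"` or `"Pre"`
#' @return numeric vector with one value per year (named by year); degC for
#'   temperatures, mm for precipitation
#' @export
preseason_aggregate <- function(climate, row, col, anchor_month, k,
                                factor = c("Tmin", "Tmax", "Pre")) {
  stopifnot(inherits(climate, "climate_cube"), k %in% 1:5,
            anchor_month %in% 1:12)
  factor <- match.arg(factor)
  arr <- switch(factor, Tmin = climate$tmin, Tmax = climate$tmax,
                Pre = climate$pre)
  months <- anchor_month - (k:1)                 # may be <= 0: previous year
  ny <- length(climate$years)
  out <- rep(NA_real_, ny)
  for (iy in seq_len(ny)) {
    vals <- numeric(0)
    ok <- TRUE
    for (m in months) {
      yy <- iy
      mm <- m
      if (mm < 1L) {
        mm <- mm + 12L
        yy <- iy - 1L
      }
      if (yy < 1L) {
        ok <- FALSE
        break
      }
      vals <- c(vals, arr[yy, month_days(mm), row, col])
    }
    if (ok) out[iy] <- if (factor == "Pre") sum(vals) else mean(vals)
  }
  names(out) <- climate$years
  out
}

# Monthly precompute: per factor an array [year, month, row, col] of monthly
# means (temperatures) or sums (precipitation). Window aggregates derived
# from these are exact (day-count-weighted), so the fast path used by the
# map-level search agrees with preseason_aggregate to rounding error.
monthly_climate <- function(climate) {
  d <- dim(climate$tmin)
  agg <- function(arr, fun) {
    out <- array(NA_real_, c(d[1], 12L, d[3], d[4]))
    for (m in 1:12) {
      sl <- arr[, month_days(m), , , drop = FALSE]
      ds <- dim(sl)
      dim(sl) <- c(ds[1], ds[2], ds[3] * ds[4])
      red <- if (fun == "mean") colMeans(aperm(sl, c(2, 1, 3)))
             else colSums(aperm(sl, c(2, 1, 3)))
      out[, m, , ] <- red
    }
    out
  }
  list(Tmin = agg(climate$tmin, "mean"), Tmax = agg(climate$tmax, "mean"),
       Pre = agg(climate$pre, "sum"), years = climate$years)
}

# Window aggregate from the monthly precompute for one pixel: numeric vector
# per year, NA where the window leaves the record.
window_from_monthly <- function(monthly, factor, row, col, anchor_month, k) {
  ny <- length(monthly$years)
  months <- anchor_month - (k:1)
  out <- rep(NA_real_, ny)
  lens <- .MONTH_LENGTHS
  for (iy in seq_len(ny)) {
    tot <- 0
    wsum <- 0
    ok <- TRUE
    for (m in months) {
      yy <- iy
      mm <- m
      if (mm < 1L) {
        mm <- mm + 12L
        yy <- iy - 1L
      }
      if (yy < 1L) {
        ok <- FALSE
        break
      }
      v <- monthly[[factor]][yy, mm, row, col]
      if (factor == "Pre") tot <- tot + v
      else {
        tot <- tot + v * lens[mm]
        wsum <- wsum + lens[mm]
      }
    }
    if (ok) out[iy] <- if (factor == "Pre") tot else tot / wsum
  }
  names(out) <- monthly$years
  out
}

#' Partial correlation by residualization
#'
#' Correlation between the OLS residuals of `y` on the two controls and of
#' `x` on the two controls, with a two-sided t-test at `n - 4` degrees of
#' freedom. Pairs with missing values in any series are dropped.
#'
#' @param y response (EGS per year)
#' @param x tested preseason series
#' @param z1,z2 the two control preseason series
#' @param n_min minimum complete years (default 10)
#' @return list `partial_r`, `p_value`, `n`, `valid`; invalid when there are
#'   too few complete years, any series has zero variance, or the controls
#'   are collinear (|r| > 0.999)
#' @export
partial_correlation <- function(y, x, z1, z2, n_min = 10) {
  ok <- is.finite(y) & is.finite(x) & is.finite(z1) & is.finite(z2)
  y <- y[ok]; x <- x[ok]; z1 <- z1[ok]; z2 <- z2[ok]
  n <- length(y)
  bad <- list(partial_r = NA_real_, p_value = NA_real_, n = n, valid = FALSE)
  if (n < n_min) return(bad)
  if (sd(y) == 0 || sd(x) == 0 || sd(z1) == 0 || sd(z2) == 0) return(bad)
  if (abs(cor(z1, z2)) > 0.999) return(bad)
  Z <- cbind(1, z1, z2)
  ry <- y - Z %*% qr.coef(qr(Z), y)
  rx <- x - Z %*% qr.coef(qr(Z), x)
  if (sd(ry) == 0 || sd(rx) == 0) return(bad)
  r <- cor(ry, rx)[1, 1]
  df <- n - 4L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(partial_r = r, p_value = 2 * pt(-abs(tt), df), n = n, valid = TRUE)
}

#' Optimal preseason window for one factor
#'
#' Evaluates the partial correlation between EGS and the factor, with the
#' other two factors (aggregated over the same window length) as controls,
#' for every window length `k = 1..max_k`; returns the `k` maximizing
#' `|partial_r|`, ties resolved to the smallest `k`.
#'
#' @param y EGS per year (aligned with the climate years)
#' @param windows list with one `[n_years x max_k]` matrix per factor of
#'   window aggregates, as built by the map-level search (see
#'   [attribution_map()]); or `NULL` to build from `climate`
#' @param climate,row,col used when `windows` is `NULL`
#' @param factor tested factor
#' @param anchor_month anchor month when building from `climate`
#' @param max_k maximum window length (default 5)
#' @param n_min minimum complete years
#' @return list `optimal_k`, `partial_r`, `p_value`, `valid`
#' @export
optimal_preseason <- function(y, windows = NULL, climate = NULL, row = NULL,
                              col = NULL, factor = "Tmin",
                              anchor_month = NULL, max_k = 5, n_min = 10) {
  if (is.null(windows)) {
    stopifnot(!is.null(climate), !is.null(anchor_month))
    windows <- lapply(CLIMATE_FACTORS, function(f)
      vapply(seq_len(max_k), function(k)
        preseason_aggregate(climate, row, col, anchor_month, k, f),
        numeric(length(y))))
    names(windows) <- CLIMATE_FACTORS
  }
  others <- setdiff(CLIMATE_FACTORS, factor)
  best <- list(optimal_k = NA_integer_, partial_r = NA_real_,
               p_value = NA_real_, valid = FALSE)
  for (k in seq_len(max_k)) {
    pc <- partial_correlation(y, windows[[factor]][, k],
                              windows[[others[1]]][, k],
                              windows[[others[2]]][, k], n_min)
    if (pc$valid &&
        (!best$valid || abs(pc$partial_r) > abs(best$partial_r))) {
      best <- list(optimal_k = k, partial_r = pc$partial_r,
                   p_value = pc$p_value, valid = TRUE)
    }
  }
  best
}

#' Standardized sensitivity regression
#'
#' OLS of EGS on the three preseason series standardized to zero mean and
#' unit variance across years; coefficients are in day per sd of each
#' factor.
#'
#' @param y EGS per year
#' @param tmin,tmax,pre preseason series at their optimal windows
#' @param n_min minimum complete years
#' @return object of class `sensitivity_result`: `coefficients` (named:
#'   Tmin, Tmax, Pre; day/sd), `intercept` (day), `r_squared`, `n`, `valid`
#' @export
sensitivity_regression <- function(y, tmin, tmax, pre, n_min = 10) {
  ok <- is.finite(y) & is.finite(tmin) & is.finite(tmax) & is.finite(pre)
  y <- y[ok]; tmin <- tmin[ok]; tmax <- tmax[ok]; pre <- pre[ok]
  n <- length(y)
  bad <- structure(list(coefficients = c(Tmin = NA_real_, Tmax = NA_real_,
                                         Pre = NA_real_),
                        intercept = NA_real_, r_squared = NA_real_, n = n,
                        valid = FALSE), class = "sensitivity_result")
  if (n < n_min) return(bad)
  if (sd(tmin) == 0 || sd(tmax) == 0 || sd(pre) == 0) return(bad)
  X <- cbind(1, zscore(tmin), zscore(tmax), zscore(pre))
  qx <- qr(X)
  if (qx$rank < 4L) return(bad)
  beta <- qr.coef(qx, y)
  fit <- X %*% beta
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum((y - fit)^2) / tss
  structure(list(coefficients = c(Tmin = beta[2], Tmax = beta[3],
                                  Pre = beta[4]),
                 intercept = beta[1], r_squared = r2, n = n, valid = TRUE),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf(
      "<sensitivity_result> Tmin %.2f, Tmax %.2f, Pre %.2f day/sd (R2 = %.2f, n = %d)\n",
      x$coefficients["Tmin"], x$coefficients["Tmax"], x$coefficients["Pre"],
      x$r_squared, x$n))
  else cat("<sensitivity_result> invalid\n")
  invisible(x)
}

#' Per-pixel optimal-window attribution map
#'
#' For every retained pixel: the anchor month is the calendar month of the
#' pixel's multi-year mean EGS; the optimal preseason window and partial
#' correlation are found per factor (controls aggregated over the same
#' window length); a standardized sensitivity regression is fitted with
#' each factor at its optimal window. A sign/significance census per factor
#' summarises the grid.
#'
#' @param cube an [egs_cube()]
#' @param climate a [climate_cube()] on the same grid
#' @param alpha significance level for the census
#' @param max_k maximum preseason window (months)
#' @param n_min minimum complete years per pixel
#' @return object of class `attribution_map`: per factor matrices
#'   `partial_r`, `p_value`, `optimal_k`; matrices `sens_<factor>`;
#'   `census` (per factor: fraction_positive, fraction_negative,
#'   fraction_positive_significant, fraction_negative_significant,
#'   n_valid); `anchor_month` matrix
#' @export
attribution_map <- function(cube, climate, alpha = 0.05, max_k = 5,
                            n_min = 10) {
  stopifnot(inherits(cube, "egs_cube"), inherits(climate, "climate_cube"),
            identical(dim(cube$egs)[2:3], dim(climate$tmin)[3:4]),
            identical(cube$years, climate$years))
  d <- dim(cube$egs)
  monthly <- monthly_climate(climate)
  partial_r <- p_value <- lapply(CLIMATE_FACTORS, function(f)
    matrix(NA_real_, d[2], d[3]))
  optimal_k <- lapply(CLIMATE_FACTORS, function(f)
    matrix(NA_integer_, d[2], d[3]))
  names(partial_r) <- names(p_value) <- names(optimal_k) <- CLIMATE_FACTORS
  sens <- lapply(CLIMATE_FACTORS, function(f) matrix(NA_real_, d[2], d[3]))
  names(sens) <- CLIMATE_FACTORS
  anchor <- matrix(NA_integer_, d[2], d[3])
  ny <- d[1]
  for (r in seq_len(d[2])) for (cl in seq_len(d[3])) {
    y <- ifelse(cube$valid[, r, cl], cube$egs[, r, cl], NA_real_)
    if (sum(is.finite(y)) < n_min) next
    am <- month_of_doy(mean(y, na.rm = TRUE))
    anchor[r, cl] <- am
    windows <- lapply(CLIMATE_FACTORS, function(f)
      vapply(seq_len(max_k), function(k)
        window_from_monthly(monthly, f, r, cl, am, k), numeric(ny)))
    names(windows) <- CLIMATE_FACTORS
    opt <- lapply(CLIMATE_FACTORS, function(f)
      optimal_preseason(y, windows = windows, factor = f, max_k = max_k,
                        n_min = n_min))
    names(opt) <- CLIMATE_FACTORS
    for (f in CLIMATE_FACTORS) {
      if (!opt[[f]]$valid) next
      partial_r[[f]][r, cl] <- opt[[f]]$partial_r
      p_value[[f]][r, cl] <- opt[[f]]$p_value
      optimal_k[[f]][r, cl] <- opt[[f]]$optimal_k
    }
    if (all(vapply(opt, `[[`, logical(1), "valid"))) {
      sr <- sensitivity_regression(y,
                                   windows$Tmin[, opt$Tmin$optimal_k],
                                   windows$Tmax[, opt$Tmax$optimal_k],
                                   windows$Pre[, opt$Pre$optimal_k], n_min)
      if (sr$valid) for (f in CLIMATE_FACTORS)
        sens[[f]][r, cl] <- sr$coefficients[f]
    }
  }
  census <- lapply(CLIMATE_FACTORS, function(f)
    attribution_census(partial_r[[f]], p_value[[f]], alpha))
  names(census) <- CLIMATE_FACTORS
  structure(list(partial_r = partial_r, p_value = p_value,
                 optimal_k = optimal_k, sensitivity = sens, census = census,
                 anchor_month = anchor, alpha = alpha, max_k = max_k),
            class = "attribution_map")
}

attribution_census <- function(r_mat, p_mat, alpha) {
  valid <- is.finite(r_mat)
  n <- sum(valid)
  frac <- function(cond) if (n == 0) NA_real_ else sum(cond & valid, na.rm = TRUE) / n
  list(fraction_positive = frac(r_mat > 0),
       fraction_negative = frac(r_mat < 0),
       fraction_positive_significant = frac(r_mat > 0 & p_mat < alpha),
       fraction_negative_significant = frac(r_mat < 0 & p_mat < alpha),
       n_valid = n)
}

#' @export
print.attribution_map <- function(x, ...) {
  cat("<attribution_map>\n")
  for (f in CLIMATE_FACTORS) {
    cs <- x$census[[f]]
    ks <- x$optimal_k[[f]][is.finite(x$optimal_k[[f]])]
    cat(sprintf(
      "  %-4s: P %.1f%% (sig %.1f%%), N %.1f%% (sig %.1f%%); modal k = %s; n = %d\n",
      f, 100 * cs$fraction_positive, 100 * cs$fraction_positive_significant,
      100 * cs$fraction_negative, 100 * cs$fraction_negative_significant,
      if (length(ks)) names(which.max(table(ks))) else "NA", cs$n_valid))
  }
  invisible(x)
}

#' Per-biome attribution and sensitivity
#'
#' Class-mean EGS and class-mean preseason series per year (the anchor is
#' the month of the class-mean EGS), then the optimal-window partial
#' correlation and standardized sensitivity at class level.
#'
#' @param cube an [egs_cube()]
#' @param climate a [climate_cube()]
#' @param landcover character class matrix on the cube grid
#' @param max_k,n_min,alpha as in [attribution_map()]
#' @return data.frame: one row per class x factor with `optimal_k`,
#'   `partial_r`, `p_value`, `sensitivity`, `r_squared`, `n_years`
#' @export
biome_attribution <- function(cube, climate, landcover, max_k = 5,
                              n_min = 10, alpha = 0.05) {
  stopifnot(identical(dim(landcover), dim(cube$egs)[2:3]))
  monthly <- monthly_climate(climate)
  ny <- length(cube$years)
  classes <- setdiff(intersect(LANDCOVER_CLASSES, unique(as.vector(landcover))),
                     "excluded")
  rows <- list()
  for (cls in classes) {
    sel <- landcover == cls
    y <- class_mean_series(cube, sel)
    if (sum(is.finite(y)) < n_min) next
    am <- month_of_doy(mean(y, na.rm = TRUE))
    idx <- which(sel)
    rc <- arrayInd(idx, dim(sel))
    windows <- lapply(CLIMATE_FACTORS, function(f) {
      acc <- matrix(0, ny, max_k)
      for (i in seq_len(nrow(rc))) {
        acc <- acc + vapply(seq_len(max_k), function(k)
          window_from_monthly(monthly, f, rc[i, 1], rc[i, 2], am, k),
          numeric(ny))
      }
      acc / nrow(rc)
    })
    names(windows) <- CLIMATE_FACTORS
    opt <- lapply(CLIMATE_FACTORS, function(f)
      optimal_preseason(y, windows = windows, factor = f, max_k = max_k,
                        n_min = n_min))
    names(opt) <- CLIMATE_FACTORS
    sr <- if (all(vapply(opt, `[[`, logical(1), "valid")))
      sensitivity_regression(y, windows$Tmin[, opt$Tmin$optimal_k],
                             windows$Tmax[, opt$Tmax$optimal_k],
                             windows$Pre[, opt$Pre$optimal_k], n_min)
    else NULL
    for (f in CLIMATE_FACTORS) {
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, factor = f, optimal_k = opt[[f]]$optimal_k,
        partial_r = opt[[f]]$partial_r, p_value = opt[[f]]$p_value,
        sensitivity = if (!is.null(sr) && sr$valid) sr$coefficients[f]
                      else NA_real_,
        r_squared = if (!is.null(sr) && sr$valid) sr$r_squared else NA_real_,
        n_years = sum(is.finite(y)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
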