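# Synthetic scene generator: double-logistic annual cycles on a grid, daily
# climate with seasonal cycles, and a planted linear dependence of the autumn
# inflection on preseason climate anomalies.

#' Parameters of a double-logistic annual cycle
#'
#' The noise-free daily curve is
#' `f(t) = base + amplitude * (plogis(k1 (t - S)) - plogis(k2 (t - A)))`
#' with `S` the spring and `A` the autumn inflection (DOY) and `k1`, `k2`
#' the transition rates (1/day). Composite observations sample the curve at
#' the composite mid-period day plus i.i.d. Gaussian noise.
#'
#' @param base background winter signal level
#' @param amplitude seasonal amplitude (> 0)
#' @param spring,autumn spring / autumn inflection DOY (`spring < autumn`,
#'   both in `[1, 366]`)
#' @param spring_rate,autumn_rate logistic rates in 1/day (> 0)
#' @param noise_sd composite observation noise sd (>= 0, signal units)
#' @return an object of class `cycle_params`
#' @export
cycle_params <- function(base = 0.1, amplitude = 0.5, spring = 100,
                         autumn = 290, spring_rate = 0.08, autumn_rate = 0.08,
                         noise_sd = 0.02) {
  stopifnot(amplitude > 0, spring < autumn, spring >= 1, autumn <= 366,
            spring_rate > 0, autumn_rate > 0, noise_sd >= 0)
  structure(list(base = base, amplitude = amplitude, spring = spring,
                 autumn = autumn, spring_rate = spring_rate,
                 autumn_rate = autumn_rate, noise_sd = noise_sd),
            class = "cycle_params")
}

#' Evaluate the noise-free double-logistic curve
#'
#' @param t day of year (real-valued allowed)
#' @param params a [cycle_params()] object
#' @param autumn optional override of the autumn inflection (vectorised with `t`)
#' @return curve values
#' @export
double_logistic <- function(t, params, autumn = params$autumn) {
  params$base + params$amplitude *
    (plogis(params$spring_rate * (t - params$spring)) -
       plogis(params$autumn_rate * (t - autumn)))
}

# Day at which the normalized (min-max) dense daily curve first crosses
# `threshold` on its descending limb; linearly interpolated between days.
# This is the extraction oracle stored in the truth table.
dense_threshold_day <- function(params, autumn = params$autumn,
                                threshold = 0.5) {
  t <- seq_len(.YEAR_DAYS)
  f <- double_logistic(t, params, autumn)
  r <- (f - min(f)) / (max(f) - min(f))
  pk <- which.max(r)
  idx <- pk:(.YEAR_DAYS - 1L)
  hit <- idx[r[idx] >= threshold & r[idx + 1L] < threshold]
  if (!length(hit)) return(NA_real_)
  j <- hit[1L]
  j + (r[j] - threshold) / (r[j] - r[j + 1L])
}

#' Coupling between preseason climate anomalies and the autumn inflection
#'
#' The realized autumn inflection of pixel p in year y is
#' `A(p, y) = A0(p) + trend * (y - mean(y)) + beta_tmin * z(Tmin_w) +
#'  beta_tmax * z(Tmax_w) + beta_pre * z(sum Pre_w) + eps`,
#' where `w` is the true preseason window of `true_window_months` whole
#' calendar months ending the month before the month containing `A0`, `z`
#' the across-year standard score of the window aggregate, and
#' `eps ~ N(0, egs_noise_sd^2)`. Betas are in days per sd of the respective
#' aggregate, mirroring how sensitivities are reported downstream.
#'
#' @param beta_tmin,beta_tmax,beta_pre planted sensitivities (day/sd)
#' @param true_window_months planted preseason window length (1..5 months)
#' @param egs_noise_sd sd of the pixel-year inflection noise (days)
#' @param trend_day_per_year planted secular EGS trend (day/yr); generator
#'   extension used to plant delays for the trend stage
#' @return an object of class `coupling_spec`
#' @export
coupling_spec <- function(beta_tmin = 0, beta_tmax = 0, beta_pre = 0,
                          true_window_months = 3L, egs_noise_sd = 0,
                          trend_day_per_year = 0) {
  stopifnot(true_window_months %in% 1:5, egs_noise_sd >= 0)
  structure(list(beta_tmin = beta_tmin, beta_tmax = beta_tmax,
                 beta_pre = beta_pre,
                 true_window_months = as.integer(true_window_months),
                 egs_noise_sd = egs_noise_sd,
                 trend_day_per_year = trend_day_per_year),
            class = "coupling_spec")
}

#' Seasonal-cycle parameters for the synthetic daily climate
#'
#' Daily climate per pixel-year is seasonal sinusoid + grid-wide year-level
#' anomaly + per-pixel daily weather noise. `tmax = tmin + diurnal_range`
#' before noise; after noise `tmax` is floored at `tmin` so the cube always
#' satisfies `tmax >= tmin`. Precipitation is floored at 0.
#'
#' @param tmin_mean,tmin_amp annual mean and half-range of Tmin (degC)
#' @param diurnal_range mean Tmax - Tmin gap (degC, > 0)
#' @param peak_doy DOY of the warm-season peak
#' @param pre_mean,pre_amp mean and half-range of daily precipitation (mm/day)
#' @param anom_sd_t sd of the grid-wide year-level temperature anomalies (degC)
#' @param anom_sd_pre relative sd of the year-level precipitation anomaly
#' @param daily_sd_t sd of per-pixel daily temperature noise (degC)
#' @param daily_sd_pre sd of per-pixel daily precipitation noise (mm/day)
#' @return an object of class `climate_params`
#' @export
climate_params <- function(tmin_mean = 12, tmin_amp = 9, diurnal_range = 8,
                           peak_doy = 200, pre_mean = 4, pre_amp = 3,
                           anom_sd_t = 0.5, anom_sd_pre = 0.15,
                           daily_sd_t = 4, daily_sd_pre = 4) {
  stopifnot(diurnal_range > 0, pre_mean >= pre_amp, anom_sd_t >= 0,
            daily_sd_t >= 0)
  structure(list(tmin_mean = tmin_mean, tmin_amp = tmin_amp,
                 diurnal_range = diurnal_range, peak_doy = peak_doy,
                 pre_mean = pre_mean, pre_amp = pre_amp,
                 anom_sd_t = anom_sd_t, anom_sd_pre = anom_sd_pre,
                 daily_sd_t = daily_sd_t, daily_sd_pre = daily_sd_pre),
            class = "climate_params")
}

#' Generate one composited pixel-year cycle
#'
#' Samples the noise-free double-logistic daily curve at each composite's
#' mid-period day and adds i.i.d. Gaussian noise; also returns the dense
#' daily noise-free curve for oracle use.
#'
#' @param params a [cycle_params()] object
#' @param year calendar year
#' @param composite_days compositing interval, 8 or 16 days
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical series
#' @return list with `series` (a [composite_series()]), `dense` (daily
#'   noise-free curve, length 365) and `true_threshold_day` (dense-curve
#'   0.5-crossing DOY on the descending limb)
#' @export
generate_annual_cycle <- function(params, year = 2000L, composite_days = 16,
                                  seed = 1L) {
  if (!composite_days %in% c(8, 16))
    stop("composite_days must be 8 or 16", call. = FALSE)
  starts <- seq(1, .YEAR_DAYS, by = composite_days)
  mids <- rep_day(starts, composite_days)
  clean <- double_logistic(mids, params)
  noise <- if (params$noise_sd > 0)
    with_seed(seed, rnorm(length(mids), 0, params$noise_sd))
  else rep(0, length(mids))
  list(series = composite_series(year, starts, clean + noise, composite_days),
       dense = double_logistic(seq_len(.YEAR_DAYS), params),
       true_threshold_day = dense_threshold_day(params))
}

#' Generate a daily GPP-like flux series
#'
#' Daily-resolution counterpart of [generate_annual_cycle()] for a single
#' eddy-covariance-like site; values are clipped at zero (GPP cannot be
#' negative).
#'
#' @param params a [cycle_params()] object (GPP units, e.g. gC m-2 d-1)
#' @param years calendar years
#' @param seed integer seed
#' @return data.frame with columns `year`, `doy`, `gpp`; attribute
#'   `"params"` carries the generating parameters
#' @export
generate_flux_series <- function(params, years = 2003:2010, seed = 1L) {
  vals <- with_seed(seed, {
    unlist(lapply(seq_along(years), function(i) {
      double_logistic(seq_len(.YEAR_DAYS), params) +
        if (params$noise_sd > 0) rnorm(.YEAR_DAYS, 0, params$noise_sd) else 0
    }))
  })
  out <- data.frame(year = rep(years, each = .YEAR_DAYS),
                    doy = rep(seq_len(.YEAR_DAYS), length(years)),
                    gpp = pmax(vals, 0))
  attr(out, "params") <- params
  out
}

# Daily seasonal cycles shared by all pixels; returns length-365 vectors.
seasonal_climate <- function(cp) {
  t <- seq_len(.YEAR_DAYS)
  season <- cos(2 * pi * (t - cp$peak_doy) / .YEAR_DAYS)
  list(tmin = cp$tmin_mean + cp$tmin_amp * season,
       pre = cp$pre_mean + cp$pre_amp * season)
}

# Resolve a per-pixel coupling: `coupling` is a coupling_spec or a named list
# of coupling_spec keyed by land-cover class.
pixel_coupling <- function(coupling, lc_class) {
  if (inherits(coupling, "coupling_spec")) return(coupling)
  cp <- coupling[[lc_class]]
  if (is.null(cp)) stop("no coupling for land-cover class ", lc_class)
  cp
}

#' Generate a full synthetic scene
#'
#' Builds daily climate, realized per pixel-year autumn inflections coupled
#' to the preseason climate, one composited signal cube per source, a
#' land-cover grid and a truth table. The planted preseason window is
#' anchored at the calendar month containing the pixel's climatological
#' autumn inflection `A0`, matching the attribution stage's anchoring.
#'
#' @param rows,cols grid size
#' @param years calendar years (>= 2)
#' @param cycle a [cycle_params()] object used for every pixel (its `autumn`
#'   is the climatological `A0` unless `a0_field` is given)
#' @param coupling a [coupling_spec()], or a named list of them keyed by
#'   land-cover class
#' @param climate a [climate_params()] object
#' @param landcover optional character matrix `rows x cols` of classes from
#'   [LANDCOVER_CLASSES]; default all `"EBF"`
#' @param sources named list of [cycle_params()] per signal source
#'   (default `list(SIF = cycle)`); each source's `autumn` offsets the
#'   realized inflection relative to `cycle$autumn`, so sources can senesce
#'   with a fixed lag (the SIF-leads-greenness structure)
#' @param a0_field optional numeric matrix of per-pixel climatological
#'   autumn inflections overriding `cycle$autumn`
#' @param composite_days compositing interval, 8 or 16
#' @param resolution grid resolution in degrees
#' @param seed integer seed; scenes are bit-reproducible
#' @return an object of class `pheno_scene`: list with `signal` (named list
#'   of [signal_cube()]), `climate` ([climate_cube()]), `landcover`, `truth`
#'   (data.frame: pixel_id, row, col, variable, year, true_A,
#'   true_threshold_day, z_tmin, z_tmax, z_pre), `coupling`, `cycle`, `seed`
#' @export
generate_scene <- function(rows, cols, years, cycle = cycle_params(),
                           coupling = coupling_spec(),
                           climate = climate_params(), landcover = NULL,
                           sources = NULL, a0_field = NULL,
                           composite_days = 16, resolution = 0.1,
                           seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, length(years) >= 2)
  if (!composite_days %in% c(8, 16))
    stop("composite_days must be 8 or 16", call. = FALSE)
  if (climate$tmin_mean >= climate$tmin_mean + climate$diurnal_range)
    stop("impossible climate spec", call. = FALSE)
  if (is.null(landcover))
    landcover <- matrix("EBF", rows, cols)
  stopifnot(all(landcover %in% LANDCOVER_CLASSES))
  if (is.null(sources)) sources <- list(SIF = cycle)
  if (is.null(names(sources)) || any(names(sources) == ""))
    stop("sources must be a named list", call. = FALSE)
  npix <- rows * cols
  ny <- length(years)

  with_seed(seed, {
    ## --- daily climate --------------------------------------------------
    seas <- seasonal_climate(climate)
    anom_tmin <- rnorm(ny, 0, climate$anom_sd_t)       # grid-wide, per year
    anom_tmax <- rnorm(ny, 0, climate$anom_sd_t)
    anom_pre <- rnorm(ny, 0, climate$anom_sd_pre)
    dimc <- c(ny, .YEAR_DAYS, rows, cols)
    seas_tmin <- aperm(array(seas$tmin, c(.YEAR_DAYS, ny, npix)), c(2, 1, 3))
    seas_pre <- aperm(array(seas$pre, c(.YEAR_DAYS, ny, npix)), c(2, 1, 3))
    dim(seas_tmin) <- dimc
    dim(seas_pre) <- dimc
    tmin <- seas_tmin + as.vector(anom_tmin) +
      array(rnorm(prod(dimc), 0, climate$daily_sd_t), dimc)
    tmax <- seas_tmin + climate$diurnal_range + as.vector(anom_tmax) +
      array(rnorm(prod(dimc), 0, climate$daily_sd_t), dimc)
    tmax <- pmax(tmax, tmin)
    pre <- pmax(seas_pre * (1 + as.vector(anom_pre)) +
                  array(rnorm(prod(dimc), 0, climate$daily_sd_pre), dimc), 0)
    clim <- climate_cube(tmax, tmin, pre, years, resolution = resolution)

    ## --- realized autumn inflections ------------------------------------
    a0 <- if (is.null(a0_field)) matrix(cycle$autumn, rows, cols)
          else { stopifnot(identical(dim(a0_field), c(rows, cols))); a0_field }
    yc <- seq_len(ny) - (ny + 1) / 2                    # centred year index
    A <- array(NA_real_, c(ny, rows, cols))
    z_store <- array(NA_real_, c(ny, rows, cols, 3),
                     dimnames = list(NULL, NULL, NULL, c("Tmin", "Tmax", "Pre")))
    for (r in seq_len(rows)) for (cl in seq_len(cols)) {
      cp <- pixel_coupling(coupling, landcover[r, cl])
      anchor <- month_of_doy(a0[r, cl])
      mm <- anchor - (cp$true_window_months:1)
      stopifnot(all(mm >= 1))                           # window within year
      days <- unlist(lapply(mm, month_days))
      ztm <- zscore(rowMeans(tmin[, days, r, cl, drop = FALSE][, , 1, 1]))
      ztx <- zscore(rowMeans(tmax[, days, r, cl, drop = FALSE][, , 1, 1]))
      zpr <- zscore(rowSums(pre[, days, r, cl, drop = FALSE][, , 1, 1]))
      eps <- if (cp$egs_noise_sd > 0) rnorm(ny, 0, cp$egs_noise_sd) else 0
      A[, r, cl] <- a0[r, cl] + cp$trend_day_per_year * yc +
        cp$beta_tmin * ztm + cp$beta_tmax * ztx + cp$beta_pre * zpr + eps
      z_store[, r, cl, 1] <- ztm
      z_store[, r, cl, 2] <- ztx
      z_store[, r, cl, 3] <- zpr
    }

    ## --- signal cubes + truth -------------------------------------------
    starts <- seq(1, .YEAR_DAYS, by = composite_days)
    mids <- rep_day(starts, composite_days)
    cubes <- list()
    truth <- list()
    for (sname in names(sources)) {
      sp <- sources[[sname]]
      lag <- sp$autumn - cycle$autumn
      As <- A + lag
      vals <- array(NA_real_, c(ny, length(starts), rows, cols))
      for (j in seq_along(mids))
        vals[, j, , ] <- double_logistic(mids[j], sp, autumn = As)
      if (sp$noise_sd > 0)
        vals <- vals + array(rnorm(length(vals), 0, sp$noise_sd), dim(vals))
      cubes[[sname]] <- signal_cube(vals, years, starts, composite_days,
                                    variable = sname, resolution = resolution)
      truth[[sname]] <- data.frame(
        pixel_id = rep(seq_len(npix), each = ny),
        row = rep(rep(seq_len(rows), times = cols), each = ny),
        col = rep(rep(seq_len(cols), each = rows), each = ny),
        variable = sname,
        year = rep(years, npix),
        true_A = as.vector(As),
        true_threshold_day = threshold_day_lookup(sp, as.vector(As)),
        z_tmin = as.vector(z_store[, , , 1]),
        z_tmax = as.vector(z_store[, , , 2]),
        z_pre = as.vector(z_store[, , , 3]))
    }
    structure(list(signal = cubes, climate = clim, landcover = landcover,
                   truth = do.call(rbind, truth), coupling = coupling,
                   cycle = cycle, climate_params = climate, seed = seed),
              class = "pheno_scene")
  })
}

#' @export
print.pheno_scene <- function(x, ...) {
  d <- dim(x$signal[[1]]$values)
  cat(sprintf("<pheno_scene> %d x %d grid, years %d-%d, sources: %s, seed %d\n",
              d[3], d[4], min(x$signal[[1]]$years), max(x$signal[[1]]$years),
              paste(names(x$signal), collapse = ", "), x$seed))
  invisible(x)
}

# Across-year standard score; zero-variance input maps to zeros.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Dense-curve threshold-crossing day as a function of the autumn inflection,
# computed exactly on a fine grid of A and interpolated. All pixel-years of
# one source share every other cycle parameter, so this is exact up to the
# 0.05-day grid of the lookup.
threshold_day_lookup <- function(params, A_values) {
  rng <- range(A_values)
  grid <- seq(rng[1] - 1, rng[2] + 1, by = 0.05)
  td <- vapply(grid, function(a) dense_threshold_day(params, autumn = a),
               numeric(1))
  approx(grid, td, xout = A_values)$y
}
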