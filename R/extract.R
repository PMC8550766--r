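# EGS extraction: dynamic-threshold (0.5 of the normalized annual range on
# the descending limb) and derivative (steepest post-peak decline) methods.
# Both operate on the smoothed composite series; interpolation uses each
# composite's representative (mid-period) day, so results are real-valued
# DOYs at sub-composite resolution.

#' Min-max normalization of a smoothed annual series
#'
#' `ratio_t = (X_t - X_min) / (X_max - X_min)` over the annual series. A
#' flat series (X_max = X_min) is flagged invalid rather than divided by
#' zero.
#'
#' @param series a smoothed [composite_series()]
#' @return a [composite_series()] of ratios in `[0, 1]`; attribute
#'   `"valid"` is `FALSE` for a flat series
#' @export
normalize_ratio <- function(series) {
  stopifnot(inherits(series, "composite_series"))
  v <- series$values
  rng <- range(v, na.rm = TRUE)
  out <- series
  if (!all(is.finite(rng)) || rng[2] - rng[1] <= 0) {
    attr(out, "valid") <- FALSE
    return(out)
  }
  out$values <- (v - rng[1]) / (rng[2] - rng[1])
  attr(out, "valid") <- TRUE
  out
}

# Scalar cores working on (representative day, value) vectors; return a
# real-valued EGS DOY or NA. Kept free of S3 plumbing so cube extraction can
# loop over tens of thousands of pixel-years cheaply.
egs_threshold_core <- function(td, v, threshold = 0.5) {
  if (anyNA(v)) return(NA_real_)
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  r <- (v - rng[1]) / (rng[2] - rng[1])
  pk <- which.max(r)
  n <- length(r)
  if (pk >= n) return(NA_real_)                     # peak at last composite
  idx <- pk:(n - 1L)
  hit <- idx[r[idx] >= threshold & r[idx + 1L] < threshold]
  if (!length(hit)) return(NA_real_)
  j <- hit[1L]
  td[j] + (r[j] - threshold) / (r[j] - r[j + 1L]) * (td[j + 1L] - td[j])
}

egs_derivative_core <- function(td, v) {
  if (anyNA(v)) return(NA_real_)
  n <- length(v)
  pk <- which.max(v)
  if (n - pk < 4L) return(NA_real_)                 # too few post-peak points
  j <- pk:(n - 1L)
  sl <- (v[j + 1L] - v[j]) / (td[j + 1L] - td[j])
  if (min(sl) >= 0) return(NA_real_)                # no decline after peak
  jmin <- j[which.min(sl)]                          # ties -> earliest
  (td[jmin] + td[jmin + 1L]) / 2
}

pheno_date <- function(year, egs, method, peak_doy) {
  structure(list(year = as.integer(year), egs = egs, method = method,
                 valid = is.finite(egs), peak_doy = peak_doy),
            class = "pheno_date")
}

#' @export
print.pheno_date <- function(x, ...) {
  cat(sprintf("<pheno_date> %d %s: EGS %s (peak DOY %.1f)\n", x$year,
              x$method, if (x$valid) sprintf("%.1f", x$egs) else "invalid",
              x$peak_doy))
  invisible(x)
}

#' EGS by the dynamic-threshold method
#'
#' The annual series is min-max normalized; the EGS is the day, linearly
#' interpolated between composites, at which the normalized ratio first
#' drops below the threshold in the descending period (all composites at or
#' after the annual maximum). Invalid when the series is flat, the maximum
#' falls on the last composite, or the ratio never drops below the
#' threshold.
#'
#' @param series a smoothed [composite_series()]
#' @param threshold normalized-ratio threshold (default 0.5)
#' @return a `pheno_date` (fields `year`, `egs`, `method`, `valid`,
#'   `peak_doy`)
#' @export
egs_dynamic_threshold <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "composite_series"), threshold > 0,
            threshold < 1)
  td <- rep_day(series$doy, series$interval)
  egs <- egs_threshold_core(td, series$values, threshold)
  pk <- td[which.max(series$values)]
  pheno_date(series$year, egs, "dynamic_threshold", pk)
}

#' EGS by the derivative method
#'
#' First differences of the smoothed series between adjacent composites,
#' restricted to the descending period (at/after the annual maximum); the
#' EGS is the midpoint day of the interval with the most negative slope,
#' ties resolved to the earliest interval. Invalid with fewer than 4
#' composites after the maximum or with no negative post-peak slope.
#'
#' @param series a smoothed [composite_series()]
#' @return a `pheno_date`
#' @export
egs_derivative <- function(series) {
  stopifnot(inherits(series, "composite_series"))
  td <- rep_day(series$doy, series$interval)
  egs <- egs_derivative_core(td, series$values)
  pk <- td[which.max(series$values)]
  pheno_date(series$year, egs, "derivative", pk)
}

#' Extract an EGS cube from a smoothed signal cube
#'
#' Applies the chosen extraction method to every pixel-year; per-pixel
#' failures (flat series, no crossing, missing data) are recorded in the
#' validity mask, never raised.
#'
#' @param cube a smoothed [signal_cube()]
#' @param method `"dynamic_threshold"` or `"derivative"`
#' @param threshold normalized-ratio threshold for the dynamic-threshold
#'   method
#' @param keep optional logical `rows x cols` retention mask from
#'   [mask_low_vegetation()]; masked pixels are invalid everywhere
#' @return an [egs_cube()]
#' @export
extract_egs_cube <- function(cube, method = c("dynamic_threshold", "derivative"),
                             threshold = 0.5, keep = NULL) {
  stopifnot(inherits(cube, "signal_cube"))
  method <- match.arg(method)
  d <- dim(cube$values)
  td <- rep_day(cube$doy, cube$interval)
  core <- if (method == "dynamic_threshold")
    function(v) egs_threshold_core(td, v, threshold)
  else function(v) egs_derivative_core(td, v)
  egs <- array(NA_real_, c(d[1], d[3], d[4]))
  for (r in seq_len(d[3])) for (cl in seq_len(d[4])) {
    if (!is.null(keep) && !keep[r, cl]) next
    vm <- cube$values[, , r, cl, drop = FALSE]
    for (y in seq_len(d[1])) egs[y, r, cl] <- core(vm[y, , 1, 1])
  }
  out <- egs_cube(egs, is.finite(egs), cube$years, method, cube$variable)
  vf <- mean(out$valid)
  message(sprintf("extract_egs_cube: %s/%s, %.1f%% of pixel-years valid",
                  cube$variable, method, 100 * vf))
  out
}
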