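# S3 containers shared across the pipeline.

#' Composite vegetation-signal series for one pixel-year
#'
#' One year of composited signal (SIF, EVI, NIRv or GPP) at a fixed
#' compositing interval. Timestamps are the DOY of the composite *start*
#' (1-based); the representative day of a composite, used for all
#' interpolation, is `timestamp + (interval - 1) / 2`.
#'
#' @param year calendar year (integer)
#' @param doy strictly increasing DOYs of composite starts
#' @param values signal values; `NA` marks missing composites
#' @param interval compositing interval in days (1 for daily series)
#' @param variable one of `"SIF"`, `"EVI"`, `"NIRv"`, `"GPP"`, `"NDVI"`, `"NIR"`
#' @return an object of class `composite_series`
#' @export
composite_series <- function(year, doy, values, interval, variable = "SIF") {
  stopifnot(length(doy) == length(values), all(diff(doy) > 0),
            interval > 0, length(doy) * interval <= 366 + interval)
  structure(list(year = as.integer(year), doy = as.numeric(doy),
                 values = as.numeric(values), interval = as.numeric(interval),
                 variable = variable),
            class = "composite_series")
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf("<composite_series> %s, year %d, %d composites @ %g d, %d missing\n",
              x$variable, x$year, length(x$values), x$interval,
              sum(is.na(x$values))))
  invisible(x)
}

# Representative (mid-period) day of each composite.
rep_day <- function(doy, interval) doy + (interval - 1) / 2

#' Gridded multi-year signal cube
#'
#' @param values 4-d array `[year, composite, row, col]`
#' @param years calendar years along dim 1
#' @param doy composite-start DOYs along dim 2
#' @param interval compositing interval (days)
#' @param variable signal tag
#' @param lat,lon cell-centre axes (degrees); lengths match dims 3 and 4
#' @param resolution grid resolution in degrees
#' @return an object of class `signal_cube`
#' @export
signal_cube <- function(values, years, doy, interval, variable = "SIF",
                        lat = NULL, lon = NULL, resolution = 0.1) {
  stopifnot(length(dim(values)) == 4L,
            dim(values)[1] == length(years), dim(values)[2] == length(doy),
            resolution > 0)
  if (is.null(lat)) lat <- seq(30, by = -resolution, length.out = dim(values)[3])
  if (is.null(lon)) lon <- seq(105, by = resolution, length.out = dim(values)[4])
  stopifnot(length(lat) == dim(values)[3], length(lon) == dim(values)[4])
  structure(list(values = values, years = as.integer(years),
                 doy = as.numeric(doy), interval = as.numeric(interval),
                 variable = variable, lat = lat, lon = lon,
                 resolution = resolution),
            class = "signal_cube")
}

#' @export
print.signal_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<signal_cube> %s: %d years x %d composites (%g d) on %d x %d grid @ %g deg\n",
              x$variable, d[1], d[2], x$interval, d[3], d[4], x$resolution))
  invisible(x)
}

# Extract one pixel-year as a composite_series.
cube_series <- function(cube, year_index, row, col) {
  composite_series(cube$years[year_index], cube$doy,
                   cube$values[year_index, , row, col],
                   cube$interval, cube$variable)
}

#' Daily gridded climate cube
#'
#' @param tmax,tmin,pre 4-d arrays `[year, day, row, col]`; temperatures in
#'   degC, precipitation in mm/day. Invariants: `tmax >= tmin`, `pre >= 0`.
#' @param years calendar years
#' @param lat,lon,resolution grid axes as in [signal_cube()]
#' @return an object of class `climate_cube`
#' @export
climate_cube <- function(tmax, tmin, pre, years, lat = NULL, lon = NULL,
                         resolution = 0.1) {
  stopifnot(identical(dim(tmax), dim(tmin)), identical(dim(tmax), dim(pre)),
            dim(tmax)[1] == length(years), dim(tmax)[2] == .YEAR_DAYS)
  structure(list(tmax = tmax, tmin = tmin, pre = pre,
                 years = as.integer(years), lat = lat, lon = lon,
                 resolution = resolution),
            class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  d <- dim(x$tmax)
  cat(sprintf("<climate_cube> %d years x %d days on %d x %d grid\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Per pixel-year EGS cube
#'
#' @param egs 3-d array `[year, row, col]` of real-valued EGS DOYs (`NA`
#'   where invalid)
#' @param valid logical array of the same shape
#' @param years calendar years
#' @param method `"dynamic_threshold"` or `"derivative"`
#' @param variable source signal tag
#' @return an object of class `egs_cube`
#' @export
egs_cube <- function(egs, valid, years, method, variable) {
  stopifnot(identical(dim(egs), dim(valid)), dim(egs)[1] == length(years))
  structure(list(egs = egs, valid = valid, years = as.integer(years),
                 method = method, variable = variable),
            class = "egs_cube")
}

#' @export
print.egs_cube <- function(x, ...) {
  d <- dim(x$egs)
  cat(sprintf("<egs_cube> %s / %s: %d years on %d x %d grid; %.1f%% valid; mean EGS %.1f\n",
              x$variable, x$method, d[1], d[2], d[3],
              100 * mean(x$valid), mean(x$egs[x$valid])))
  invisible(x)
}

#' Land-cover classes recognised by the per-biome summaries
#' @export
LANDCOVER_CLASSES <- c("ECF", "EBF", "DBF", "shrub", "grassland", "excluded")
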