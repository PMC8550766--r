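# Preprocessing: maximum-value compositing 8 -> 16 days, Savitzky-Golay
# smoothing, NIRv, low-vegetation masking, grid aggregation.

#' Maximum-value compositing from 8-day to 16-day composites
#'
#' Each 16-day value is the maximum of its two constituent 8-day values,
#' skipping missing values; the output is missing only when both inputs are
#' missing. A 16-day input is returned unchanged (idempotence).
#'
#' @param series a [composite_series()] at 8-day (or already 16-day) interval
#' @param target_interval target interval in days (16)
#' @return a [composite_series()] at 16-day interval
#' @export
composite_max <- function(series, target_interval = 16) {
  stopifnot(inherits(series, "composite_series"), target_interval == 16)
  if (series$interval == target_interval) return(series)
  if (series$interval != 8)
    stop("composite_max expects an 8-day input series", call. = FALSE)
  n16 <- floor(length(series$values) / 2)
  i1 <- 2 * seq_len(n16) - 1
  v <- pmax(series$values[i1], series$values[i1 + 1], na.rm = TRUE)
  v[is.na(series$values[i1]) & is.na(series$values[i1 + 1])] <- NA
  composite_series(series$year, series$doy[i1], v, 16, series$variable)
}

#' @rdname composite_max
#' @param cube a [signal_cube()] at 8-day interval
#' @export
composite_max_cube <- function(cube, target_interval = 16) {
  stopifnot(inherits(cube, "signal_cube"))
  if (cube$interval == target_interval) return(cube)
  if (cube$interval != 8)
    stop("composite_max expects an 8-day input cube", call. = FALSE)
  n16 <- floor(dim(cube$values)[2] / 2)
  i1 <- 2 * seq_len(n16) - 1
  a <- cube$values[, i1, , , drop = FALSE]
  b <- cube$values[, i1 + 1, , , drop = FALSE]
  v <- pmax(a, b, na.rm = TRUE)
  v[is.na(a) & is.na(b)] <- NA
  signal_cube(v, cube$years, cube$doy[i1], 16, cube$variable,
              cube$lat, cube$lon, cube$resolution)
}

# Savitzky-Golay applied through the projection matrix of signal::sgolay:
# interior points use the centre row, the first/last k points the edge rows
# fitted on the leading/trailing full window (identical to signal::sgolayfilt).
sg_apply <- function(x, F) {
  n <- nrow(F)
  k <- (n - 1L) / 2L
  len <- length(x)
  out <- numeric(len)
  for (j in seq_len(k)) out[j] <- sum(F[j, ] * x[1:n])
  cf <- F[k + 1L, ]
  for (j in (k + 1L):(len - k)) out[j] <- sum(cf * x[(j - k):(j + k)])
  for (j in seq_len(k))
    out[len - k + j] <- sum(F[k + 1L + j, ] * x[(len - n + 1L):len])
  out
}

# Row-wise SG smoothing of a series matrix [series, time]; no NAs allowed.
sg_apply_matrix <- function(M, F) {
  n <- nrow(F)
  k <- (n - 1L) / 2L
  len <- ncol(M)
  out <- matrix(NA_real_, nrow(M), len)
  for (j in seq_len(k)) out[, j] <- M[, 1:n, drop = FALSE] %*% F[j, ]
  cf <- F[k + 1L, ]
  for (j in (k + 1L):(len - k))
    out[, j] <- M[, (j - k):(j + k), drop = FALSE] %*% cf
  for (j in seq_len(k))
    out[, len - k + j] <- M[, (len - n + 1L):len, drop = FALSE] %*% F[k + 1L + j, ]
  out
}

# Linear time-interpolation of missing composites (flat extrapolation at the
# edges). Returns NULL when the gap fraction exceeds `max_gap_frac`.
fill_gaps <- function(doy, values, max_gap_frac = 0.3) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  if (mean(miss) > max_gap_frac || sum(!miss) < 4) return(NULL)
  approx(doy[!miss], values[!miss], xout = doy, rule = 2)$y
}

#' Savitzky-Golay smoothing of a composite series
#'
#' Missing composites are linearly interpolated in time first; a series with
#' more than 30% missing (or fewer than 4 observed) composites is flagged
#' invalid rather than smoothed, as is a series shorter than the window.
#'
#' @param series a [composite_series()]
#' @param window odd window length in composites (> `polyorder`)
#' @param polyorder polynomial order of the local fit
#' @return a [composite_series()] with identical timestamps; attribute
#'   `"valid"` is `FALSE` when the series could not be smoothed
#' @export
smooth_savitzky_golay <- function(series, window = 7, polyorder = 3) {
  stopifnot(inherits(series, "composite_series"),
            window %% 2 == 1, window > polyorder)
  bad <- function() {
    out <- series
    attr(out, "valid") <- FALSE
    out
  }
  if (length(series$values) < window) return(bad())
  v <- fill_gaps(series$doy, series$values)
  if (is.null(v)) return(bad())
  F <- signal::sgolay(p = polyorder, n = window)
  out <- composite_series(series$year, series$doy, sg_apply(v, F),
                          series$interval, series$variable)
  attr(out, "valid") <- TRUE
  out
}

#' @rdname smooth_savitzky_golay
#' @param cube a [signal_cube()]
#' @export
smooth_cube <- function(cube, window = 7, polyorder = 3) {
  stopifnot(inherits(cube, "signal_cube"))
  d <- dim(cube$values)
  F <- signal::sgolay(p = polyorder, n = window)
  M <- matrix(aperm(cube$values, c(1, 3, 4, 2)), ncol = d[2])
  miss <- which(rowSums(is.na(M)) > 0)
  for (i in miss) {
    v <- fill_gaps(cube$doy, M[i, ])
    M[i, ] <- if (is.null(v)) NA_real_ else v
  }
  ok <- rowSums(is.na(M)) == 0
  S <- matrix(NA_real_, nrow(M), d[2])
  if (any(ok)) S[ok, ] <- sg_apply_matrix(M[ok, , drop = FALSE], F)
  out <- aperm(array(S, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  signal_cube(out, cube$years, cube$doy, cube$interval, cube$variable,
              cube$lat, cube$lon, cube$resolution)
}

#' NIRv from NDVI and NIR reflectance
#'
#' Elementwise product of NDVI and near-infrared reflectance on aligned
#' timestamps; missing values propagate.
#'
#' @param ndvi,nir_reflectance aligned [composite_series()] objects
#' @return a [composite_series()] tagged `NIRv`
#' @export
compute_nirv <- function(ndvi, nir_reflectance) {
  stopifnot(inherits(ndvi, "composite_series"),
            inherits(nir_reflectance, "composite_series"))
  if (!isTRUE(all.equal(ndvi$doy, nir_reflectance$doy)) ||
      ndvi$interval != nir_reflectance$interval)
    stop("NDVI and NIR series are not aligned", call. = FALSE)
  composite_series(ndvi$year, ndvi$doy, ndvi$values * nir_reflectance$values,
                   ndvi$interval, "NIRv")
}

#' Low-vegetation mask from multi-year mean EVI
#'
#' A pixel is excluded when its multi-year mean EVI is strictly below the
#' threshold (values exactly at the threshold are retained); all-missing
#' pixels are excluded with a warning.
#'
#' @param cube an EVI [signal_cube()]
#' @param threshold mask threshold (default 0.08)
#' @return logical matrix `rows x cols`; `TRUE` = retained
#' @export
mask_low_vegetation <- function(cube, threshold = 0.08) {
  stopifnot(inherits(cube, "signal_cube"))
  m <- apply(cube$values, c(3, 4), mean, na.rm = TRUE)  # NaN if all missing
  nall <- sum(is.nan(m))
  if (nall > 0)
    warning(nall, " all-missing pixel(s) excluded from the vegetation mask")
  keep <- !is.nan(m) & m >= threshold
  keep
}

#' Aggregate a fine cube to a coarser grid by block means
#'
#' Each coarse cell is the arithmetic mean of its k x k fine cells, skipping
#' missing values; a coarse cell is missing only when all fine cells are.
#'
#' @param cube a [signal_cube()]
#' @param target_resolution coarse resolution; must be an integer multiple
#'   of `cube$resolution`, and the grid dimensions must be divisible by the
#'   ratio
#' @return a [signal_cube()] at `target_resolution`
#' @export
aggregate_to_grid <- function(cube, target_resolution = 0.1) {
  stopifnot(inherits(cube, "signal_cube"))
  ratio <- target_resolution / cube$resolution
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("target resolution must be an integer multiple of the source",
         call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(cube)
  d <- dim(cube$values)
  if (d[3] %% ratio != 0 || d[4] %% ratio != 0)
    stop("grid dimensions not divisible by the aggregation ratio",
         call. = FALSE)
  nr <- d[3] %/% ratio
  nc <- d[4] %/% ratio
  out <- array(0, c(d[1], d[2], nr, nc))
  cnt <- array(0L, c(d[1], d[2], nr, nc))
  for (i in seq_len(ratio)) for (j in seq_len(ratio)) {
    sub <- cube$values[, , seq(i, d[3], by = ratio), seq(j, d[4], by = ratio),
                       drop = FALSE]
    ok <- !is.na(sub)
    sub[!ok] <- 0
    out <- out + sub
    cnt <- cnt + ok
  }
  out <- out / cnt                    # 0/0 -> NaN where all fine cells missing
  out[cnt == 0L] <- NA
  lat <- colMeans(matrix(cube$lat, nrow = ratio))
  lon <- colMeans(matrix(cube$lon, nrow = ratio))
  signal_cube(out, cube$years, cube$doy, cube$interval, cube$variable,
              lat, lon, target_resolution)
}
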