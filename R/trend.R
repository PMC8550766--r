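# Per-pixel and per-biome linear EGS trends with a sign/significance census.

#' Linear trend of EGS over calendar years
#'
#' Ordinary least squares of EGS on calendar year with a two-sided t-test on
#' the slope. A zero-variance EGS series yields slope 0 with p = 1 by
#' contract; fewer than `n_min` valid years yields an invalid result.
#'
#' @param years calendar years
#' @param egs EGS DOYs (`NA` allowed; pairs with `NA` are dropped)
#' @param n_min minimum number of valid years (default 10)
#' @return object of class `trend_result`: `slope` (day/yr), `intercept`
#'   (day, at year 0), `p_value`, `n_years`, `valid`
#' @export
linear_trend <- function(years, egs, n_min = 10) {
  ok <- is.finite(years) & is.finite(egs)
  x <- years[ok]
  y <- egs[ok]
  n <- length(y)
  res <- function(slope, intercept, p, valid)
    structure(list(slope = slope, intercept = intercept, p_value = p,
                   n_years = n, valid = valid), class = "trend_result")
  if (n < n_min || var(x) == 0)
    return(res(NA_real_, NA_real_, NA_real_, FALSE))
  if (var(y) == 0) return(res(0, y[1], 1, TRUE))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(-abs(slope / se), df = n - 2)
  res(slope, intercept, p, TRUE)
}

#' @export
print.trend_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<trend_result> slope %.3f day/yr (p = %.3g, n = %d)\n",
                x$slope, x$p_value, x$n_years))
  else cat("<trend_result> invalid (too few years)\n")
  invisible(x)
}

#' Per-pixel trend map with sign/significance census
#'
#' @param cube an [egs_cube()]
#' @param alpha significance level for the census (default 0.05; raw
#'   p-values, no multiple-testing correction)
#' @param n_min minimum valid years per pixel
#' @return object of class `trend_map`: matrices `slope`, `p_value`,
#'   logical `valid`, and `census` (class `trend_census` with fields
#'   `fraction_positive`, `fraction_negative`,
#'   `fraction_positive_significant`, `fraction_negative_significant`,
#'   `n_valid`, `alpha`)
#' @export
trend_map <- function(cube, alpha = 0.05, n_min = 10) {
  stopifnot(inherits(cube, "egs_cube"))
  d <- dim(cube$egs)
  slope <- p <- matrix(NA_real_, d[2], d[3])
  for (r in seq_len(d[2])) for (cl in seq_len(d[3])) {
    tr <- linear_trend(cube$years, cube$egs[, r, cl], n_min)
    if (tr$valid) {
      slope[r, cl] <- tr$slope
      p[r, cl] <- tr$p_value
    }
  }
  valid <- is.finite(slope)
  structure(list(slope = slope, p_value = p, valid = valid,
                 census = trend_census(slope, p, valid, alpha)),
            class = "trend_map")
}

trend_census <- function(slope, p, valid, alpha) {
  n <- sum(valid)
  frac <- function(cond) if (n == 0) NA_real_ else sum(cond & valid, na.rm = TRUE) / n
  structure(list(fraction_positive = frac(slope > 0),
                 fraction_negative = frac(slope < 0),
                 fraction_positive_significant = frac(slope > 0 & p < alpha),
                 fraction_negative_significant = frac(slope < 0 & p < alpha),
                 n_valid = n, alpha = alpha),
            class = "trend_census")
}

#' @export
print.trend_census <- function(x, ...) {
  cat(sprintf(
    "<trend_census> n = %d: P %.1f%% (sig %.1f%%), N %.1f%% (sig %.1f%%) at alpha = %g\n",
    x$n_valid, 100 * x$fraction_positive, 100 * x$fraction_positive_significant,
    100 * x$fraction_negative, 100 * x$fraction_negative_significant, x$alpha))
  invisible(x)
}

#' @export
print.trend_map <- function(x, ...) {
  cat(sprintf("<trend_map> %d x %d pixels, %d valid\n",
              nrow(x$slope), ncol(x$slope), x$census$n_valid))
  print(x$census)
  invisible(x)
}

#' Per-biome EGS trends
#'
#' EGS is averaged over the valid pixels of each land-cover class per year
#' (the class-mean series), then a single linear trend is fitted per class.
#'
#' @param cube an [egs_cube()]
#' @param landcover character matrix of classes matching the cube grid
#' @param n_min minimum valid years for the class-mean trend
#' @return data.frame with one row per non-excluded class present:
#'   `class`, `slope`, `p_value`, `n_years`, `n_pixels`, `valid`
#' @export
biome_trend <- function(cube, landcover, n_min = 10) {
  stopifnot(inherits(cube, "egs_cube"),
            identical(dim(landcover), dim(cube$egs)[2:3]))
  classes <- setdiff(intersect(LANDCOVER_CLASSES, unique(as.vector(landcover))),
                     "excluded")
  out <- lapply(classes, function(cls) {
    sel <- landcover == cls
    ym <- class_mean_series(cube, sel)
    tr <- linear_trend(cube$years, ym, n_min)
    data.frame(class = cls, slope = tr$slope, p_value = tr$p_value,
               n_years = tr$n_years, n_pixels = sum(sel), valid = tr$valid)
  })
  do.call(rbind, out)
}

# Year-wise mean EGS over the selected pixels, skipping invalid pixel-years.
class_mean_series <- function(cube, sel) {
  ny <- dim(cube$egs)[1]
  vapply(seq_len(ny), function(y) {
    v <- cube$egs[y, , ][sel & cube$valid[y, , ]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}
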