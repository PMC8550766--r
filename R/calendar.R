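# 365-day calendar helpers (no leap years in synthetic mode).

.MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_STARTS <- c(0L, cumsum(.MONTH_LENGTHS))[1:12] + 1L  # DOY of month start
.YEAR_DAYS <- 365L

#' Calendar month containing a day of year
#'
#' @param doy day-of-year, 1-based; values are clamped to `[1, 365]`
#'   (DOY 366 maps to December).
#' @return integer month in 1..12
#' @export
month_of_doy <- function(doy) {
  doy <- pmin(pmax(round(doy), 1L), .YEAR_DAYS)
  findInterval(doy, .MONTH_STARTS)
}

#' Days of year belonging to a calendar month
#'
#' @param month integer in 1..12
#' @return integer vector of DOYs
#' @export
month_days <- function(month) {
  stopifnot(length(month) == 1L, month >= 1L, month <= 12L)
  seq.int(.MONTH_STARTS[month], length.out = .MONTH_LENGTHS[month])
}

# Evaluate code with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards, so generators are bit-reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
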