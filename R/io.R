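# Plain-text (CSV/YAML) persistence for cubes, tables and configs.

#' Write / read an EGS cube as long-format CSV
#'
#' Columns: `year`, `row`, `col`, `egs`, `valid`; method and source tags and
#' grid shape travel in a `# key: value` comment header.
#'
#' @param cube an [egs_cube()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_egs_csv <- function(cube, path) {
  d <- dim(cube$egs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", cube$method), con)
  writeLines(sprintf("# variable: %s", cube$variable), con)
  writeLines(sprintf("# grid: %d %d", d[2], d[3]), con)
  df <- data.frame(
    year = rep(cube$years, times = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    egs = round(as.vector(cube$egs), 4),
    valid = as.vector(cube$valid))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_egs_csv
#' @export
read_egs_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- sub("^# [a-z]+: ", "", hdr)
  grid <- as.integer(strsplit(meta[3], " ")[[1]])
  df <- read.csv(path, comment.char = "#")
  years <- sort(unique(df$year))
  df <- df[order(df$col, df$row, df$year), ]
  egs <- array(df$egs, c(length(years), grid[1], grid[2]))
  valid <- array(df$valid, c(length(years), grid[1], grid[2]))
  egs_cube(egs, valid, years, meta[1], meta[2])
}

#' Analysis configuration
#'
#' Collects the pipeline's tunables with their standard defaults: a 0.5
#' dynamic threshold, an EVI mask threshold of 0.08 (strict `<`), up to 5
#' preseason months, alpha 0.05 and a 0.1 degree analysis grid.
#'
#' @param rows,cols,years synthetic demo-scene shape
#' @param seed integer seed for the whole run
#' @param composite_days native compositing interval (8 or 16)
#' @param sg_window,sg_order Savitzky-Golay window (composites) and order
#' @param threshold dynamic-threshold ratio
#' @param methods extraction methods to run
#' @param alpha significance level
#' @param n_min minimum valid years per pixel statistic
#' @param max_preseason_months maximum preseason window (months)
#' @param mask_threshold EVI mask threshold
#' @param target_resolution analysis grid resolution (degrees)
#' @param attribution_source signal source attributed to climate
#' @param source_lag_days planted senescence lag of the greenness (EVI)
#'   source behind SIF in the demo scene
#' @param beta_tmin,beta_tmax,beta_pre,true_window_months,egs_noise_sd,trend_day_per_year
#'   planted coupling of the demo scene (see [coupling_spec()])
#' @param signal_noise_sd composite observation noise of the demo scene
#' @param include_flux also simulate and compare a daily GPP flux site
#' @param flux_lead_days days by which the flux-site GPP senesces ahead of
#'   the SIF source
#' @param out_dir directory for persisted intermediates (`NULL` = tempdir)
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(rows = 20, cols = 20, years = 2000:2018,
                            seed = 1L, composite_days = 16,
                            sg_window = 7, sg_order = 3, threshold = 0.5,
                            methods = c("dynamic_threshold", "derivative"),
                            alpha = 0.05, n_min = 10,
                            max_preseason_months = 5, mask_threshold = 0.08,
                            target_resolution = 0.1,
                            attribution_source = "SIF",
                            source_lag_days = 14, beta_tmin = 2,
                            beta_tmax = -1, beta_pre = 0.5,
                            true_window_months = 3, egs_noise_sd = 3,
                            trend_day_per_year = 0, signal_noise_sd = 0.02,
                            include_flux = TRUE, flux_lead_days = 12,
                            out_dir = NULL) {
  stopifnot(threshold > 0, threshold < 1, mask_threshold >= 0,
            alpha > 0, alpha < 1, max_preseason_months %in% 1:5,
            composite_days %in% c(8, 16), n_min >= 3,
            all(methods %in% c("dynamic_threshold", "derivative")))
  structure(list(rows = rows, cols = cols, years = years, seed = as.integer(seed),
                 composite_days = composite_days, sg_window = sg_window,
                 sg_order = sg_order, threshold = threshold,
                 methods = methods, alpha = alpha, n_min = n_min,
                 max_preseason_months = max_preseason_months,
                 mask_threshold = mask_threshold,
                 target_resolution = target_resolution,
                 attribution_source = attribution_source,
                 source_lag_days = source_lag_days, beta_tmin = beta_tmin,
                 beta_tmax = beta_tmax, beta_pre = beta_pre,
                 true_window_months = true_window_months,
                 egs_noise_sd = egs_noise_sd,
                 trend_day_per_year = trend_day_per_year,
                 signal_noise_sd = signal_noise_sd,
                 include_flux = include_flux, flux_lead_days = flux_lead_days,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`
#' @param path YAML file path
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$years <- as.integer(x$years)
  x$out_dir <- NULL          # run-local location, not part of the analysis
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$years)) x$years <- as.integer(unlist(x$years))
  do.call(analysis_config, x)
}
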