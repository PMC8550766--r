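# Shared fixtures, built in code at test time.

# Random quantized series: values are exact multiples of 2^-26, so that
# affine transforms with power-of-two slopes and quantum-aligned intercepts
# are applied without any floating-point rounding (see the affine-invariance
# tests: they assert the extractor's algebraic invariance bit-exactly).
quantized_series <- function(n = 23, seed = 1) {
  set.seed(seed)
  q <- 2^-26
  v <- round(runif(n) / q) * q
  composite_series(2000, seq(1, by = 16, length.out = n), v, 16)
}

# One smoothed noise-free 16-day cycle plus its dense oracle.
smooth_cycle <- function(autumn = 290, k2 = 0.08, noise_sd = 0, seed = 1) {
  p <- cycle_params(autumn = autumn, autumn_rate = k2, noise_sd = noise_sd)
  cyc <- generate_annual_cycle(p, 2000, 16, seed)
  list(smoothed = smooth_savitzky_golay(cyc$series),
       raw = cyc$series, dense = cyc$dense,
       true_threshold_day = cyc$true_threshold_day, params = p)
}

# A small coupled scene reused across attribution tests.
small_coupled_scene <- function(rows = 10, cols = 10, seed = 42,
                                egs_noise_sd = 3) {
  generate_scene(rows, cols, 2000:2018,
                 coupling = coupling_spec(beta_tmin = 2, beta_tmax = -1,
                                          beta_pre = 0.5,
                                          true_window_months = 3,
                                          egs_noise_sd = egs_noise_sd),
                 seed = seed)
}
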