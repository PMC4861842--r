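# Shared fixtures for the suite: all synthetic, built in code.

# a barn small enough for fast tests but with both lameness groups
tiny_config <- function(seed = 1, ...) {
  barn_config(seed = seed, n_nonlame = 2, n_lame = 3, n_days = 4, ...)
}

# degenerate config: no between-cow or day-level variation anywhere
degenerate_config <- function(seed = 1, ...) {
  barn_config(seed = seed,
              feed_freq_sd = c(0, 0), feed_rate_sd = c(0, 0),
              fmi_sd = c(0, 0), milk_sd = c(0, 0), milk_day_sd = c(0, 0),
              rum_cow_sd = 0, rum_day_sd = 0, dim_sd = 0,
              dim_trend_freq_lame = 0, score_inconsistent_p = 0, ...)
}

# one cow's visits lying exactly on a given origin line (kg/s)
visits_on_line <- function(durations_s, slope_kg_s, cow_id = 1) {
  data.frame(cow_id = cow_id, duration_s = durations_s,
             fmi_kg = durations_s * slope_kg_s)
}

# build an accel_signal object directly from a sample matrix
signal_from_matrix <- function(m, fs = 12) {
  structure(list(cow_id = 1, fs = fs, t0 = 0, samples = m),
            class = "accel_signal")
}

# random-intercept test data with known structure
ri_data <- function(n_g, n_per, beta = c(2, 1.5, -0.8), sd_g = 1.2,
                    sd_e = 0.7, seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(g = rep(seq_len(n_g), each = n_per),
                    x = stats::rnorm(n_g * n_per),
                    f = stats::rbinom(n_g * n_per, 1, 0.5) == 1)
    d$y <- beta[1] + beta[2] * d$x + beta[3] * d$f +
      rep(stats::rnorm(n_g, 0, sd_g), each = n_per) +
      stats::rnorm(nrow(d), 0, sd_e)
    d
  })
}
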