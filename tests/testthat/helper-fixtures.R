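# Shared fixtures: a small reference fish, noise-free sensing, and a
# reduced-duration trial configuration that keeps unit tests fast while
# preserving the 5 min / 3 min cycle structure.

test_fish <- function(id = "f1", mass_kg = 0.012, sl_m = 0.08,
                      mode = "BCF") {
  fish_record(id, "Testfish", mode, mass_kg = mass_kg,
              standard_length_m = sl_m)
}

sensor_silent <- function() {
  sensor_model(noise_sd = 0, background_rate_0 = 0, background_slope = 0)
}

phys_default <- function(...) fish_physiology(...)

# exact straight-line trace: o2 = intercept - slope * t, all "measure"
line_trace <- function(slope = 4e-4, intercept = 6.5, dur = 300, dt = 2,
                       sat = 6.2) {
  tt <- seq(0, dur - dt, by = dt)
  oxygen_trace("lt", "rest", tt, intercept - slope * tt,
               phase = rep("measure", length(tt)), sat_conc = sat)
}

# brute-force OLS via stats::lm, the independent slope oracle
lm_slope <- function(trace, window) {
  d <- trace$data[trace$data$time_s >= window[1] &
                    trace$data$time_s < window[2], ]
  unname(-stats::coef(stats::lm(o2 ~ time_s, data = d))[2])
}

# independent exhaustive steepest-window enumeration built on lm_slope
exhaustive_steepest <- function(trace, span, window_len = 60, stride = 2) {
  starts <- seq(span[1], span[2] - window_len, by = stride)
  slopes <- vapply(starts, function(s) lm_slope(trace, c(s, s + window_len)),
                   numeric(1))
  starts[which.max(slopes)]
}

random_measure_trace <- function(n_s = 120, dt = 2, sat = 6.2) {
  tt <- seq(0, n_s - dt, by = dt)
  # random smooth decline + noise; always positive
  base <- sat - cumsum(stats::runif(length(tt), 0, 2e-3))
  o2 <- pmax(base + stats::rnorm(length(tt), 0, 5e-3), 0.1)
  oxygen_trace("rnd", "rest", tt, o2, phase = rep("measure", length(tt)),
               sat_conc = sat)
}
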