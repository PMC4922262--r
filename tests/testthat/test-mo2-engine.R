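test_that("window segmentation follows labels, trimming and the partial-window rule", {
  tt <- seq(0, 958, by = 2)
  ph <- derive_phases(tt, cycle_schedule())
  tr <- oxygen_trace("w", "rest", tt, rep(6, length(tt)), phase = ph)
  w0 <- segment_windows(tr)
  expect_equal(nrow(w0), 2)
  expect_equal(w0$end_s - w0$start_s, c(300, 300))

  w30 <- segment_windows(tr, trim_lead_s = 30)
  expect_equal(w30$start_s, c(30, 510))
  expect_equal(w30$end_s - w30$start_s, c(270, 270))

  # trace ending 90 s into a third measurement keeps a 90 s window
  tt3 <- seq(0, 1048, by = 2)
  tr3 <- oxygen_trace("w3", "rest", tt3, rep(6, length(tt3)),
                      phase = derive_phases(tt3, cycle_schedule()))
  w3 <- segment_windows(tr3)
  expect_equal(nrow(w3), 3)
  expect_equal(w3$end_s[3] - w3$start_s[3], 90)

  # ...but a 40 s trailing fragment is dropped
  tt4 <- seq(0, 998, by = 2)
  tr4 <- oxygen_trace("w4", "rest", tt4, rep(6, length(tt4)),
                      phase = derive_phases(tt4, cycle_schedule()))
  expect_equal(nrow(segment_windows(tr4)), 2)

  tr_f <- oxygen_trace("f", "rest", tt[1:50], rep(6, 50),
                       phase = rep("flush", 50))
  expect_warning(w <- segment_windows(tr_f), "no measurement phase")
  expect_equal(nrow(w), 0)
})

test_that("slope fitting matches exact lines, flat traces and the lm oracle under noise", {
  tr <- line_trace(slope = 4e-4, intercept = 6.5)
  sl <- fit_slope(tr, c(0, 300))
  expect_equal(sl$S, 4e-4, tolerance = 1e-12)
  expect_equal(sl$intercept, 6.5, tolerance = 1e-9)
  expect_equal(sl$r2, 1, tolerance = 1e-12)

  flat <- line_trace(slope = 0, intercept = 6.0)
  sf <- fit_slope(flat, c(0, 300))
  expect_equal(sf$S, 0)
  expect_true(is.na(sf$r2))

  withr::local_seed(5)
  tt <- seq(0, 298, by = 2)
  o2 <- 6.5 - 4e-4 * tt + stats::rnorm(length(tt), 0, 0.005)
  trn <- oxygen_trace("n", "rest", tt, o2,
                      phase = rep("measure", length(tt)))
  sn <- fit_slope(trn, c(0, 300))
  # against the independent lm refit
  expect_equal(sn$S, lm_slope(trn, c(0, 300)), tolerance = 1e-12)
  # within 3 standard errors of truth (se = sd / sqrt(Sxx))
  se <- 0.005 / sqrt(sum((tt - mean(tt))^2))
  expect_lt(abs(sn$S - 4e-4), 3 * se)

  expect_error(fit_slope(tr, c(0, 4)), "< 3")
})

test_that("MO2 conversion applies volumes, mass and background correction correctly", {
  fish <- fish_record("m", "Sp", "BCF", mass_kg = 0.015,
                      standard_length_m = 0.08, body_volume_l = 0.1)
  ch <- chamber_spec("rest", volume_l = 1.6)   # v_resp = 1.5 L
  sl <- data.frame(start_s = 0, end_s = 300, S = 5e-4, intercept = 6.5,
                   r2 = 1, n_points = 150, o2_min = 6.0,
                   sat_frac_min = 6.0 / 6.2)
  e <- compute_mo2(sl, fish, ch)
  expect_equal(e$mo2, 0.0005 * 1.5 / 0.015 * 3600)   # 180 by hand
  expect_equal(e$mo2, 180)

  # background equal to the uptake cancels exactly
  bg_eq <- background_model(rate_pre = 5e-4 * 1.5 * 3600,
                            rate_post = 5e-4 * 1.5 * 3600, t_post = 600)
  e0 <- compute_mo2(sl, fish, ch, bg_eq)
  expect_equal(e0$mo2, 0)

  # midpoint interpolation: window midpoint halfway between pre and post
  bg <- background_model(rate_pre = 0.01, rate_post = 0.03, t_pre = 0,
                         t_post = 300)
  expect_equal(interpolate_background(bg, 150), 0.02)
  expect_equal(interpolate_background(bg, 0), 0.01)
  expect_equal(interpolate_background(bg, 300), 0.03)

  # over-correction floors at zero with a flag
  bg_big <- background_model(rate_pre = 10, rate_post = 10, t_post = 600)
  eb <- compute_mo2(sl, fish, ch, bg_big)
  expect_equal(eb$mo2, 0)
  expect_match(eb$flags, "background_overcorrection")

  fish_big <- fish_record("big", "Sp", "BCF", mass_kg = 2,
                          standard_length_m = 0.3)
  expect_error(compute_mo2(sl, fish_big, ch), "non-positive effective volume")
})

test_that("mass-specific rates scale as 1/mass and v_resp (units round-trip)", {
  sl <- data.frame(start_s = 0, end_s = 300, S = 5e-4, intercept = 6.5,
                   r2 = 1, n_points = 150, o2_min = 6, sat_frac_min = 0.97)
  f1 <- fish_record("a", "Sp", "BCF", 0.015, 0.08, body_volume_l = 0.1)
  f2 <- fish_record("b", "Sp", "BCF", 0.030, 0.08, body_volume_l = 0.1)
  ch <- chamber_spec("rest", 1.6)
  ch2 <- chamber_spec("rest", 3.1)   # doubles v_resp to 3.0
  expect_equal(compute_mo2(sl, f2, ch)$mo2, compute_mo2(sl, f1, ch)$mo2 / 2)
  expect_equal(compute_mo2(sl, f1, ch2)$mo2, compute_mo2(sl, f1, ch)$mo2 * 2)
})

test_that("steepest-window search equals independent exhaustive enumeration", {
  fish <- test_fish()
  ch <- chamber_spec("rest", 1.6)
  withr::local_seed(21)
  for (i in 1:25) {
    tr <- random_measure_trace(n_s = 180)
    got <- steepest_window_mo2(tr, c(0, 180), fish = fish, chamber = ch)
    expect_equal(got$window[1], exhaustive_steepest(tr, c(0, 180)))
  }

  # monotone exponential decay: steepest window starts at the span start
  tt <- seq(0, 298, by = 2)
  dec <- oxygen_trace("d", "rest", tt, 2 + 4 * exp(-tt / 200),
                      phase = rep("measure", length(tt)))
  gd <- steepest_window_mo2(dec, c(0, 300), fish = fish, chamber = ch)
  expect_equal(gd$window[1], 0)

  # exactly linear trace: every window ties; earliest wins
  lin <- line_trace(slope = 4e-4, dur = 300)
  gl <- steepest_window_mo2(lin, c(0, 300), fish = fish, chamber = ch)
  expect_equal(gl$window[1], 0)

  # piecewise trace, steepest segment in minute 3
  o2p <- 6.5 - cumsum(c(rep(1e-4, 60), rep(5e-4, 30), rep(1e-4, 60)) * 2)
  trp <- oxygen_trace("p", "rest", seq(0, 298, 2), o2p,
                      phase = rep("measure", 150))
  gp <- steepest_window_mo2(trp, c(0, 300), fish = fish, chamber = ch)
  expect_equal(gp$window[1], exhaustive_steepest(trp, c(0, 300)))
  expect_true(gp$window[1] >= 100 && gp$window[1] <= 180)

  expect_error(steepest_window_mo2(lin, c(0, 30), fish = fish, chamber = ch),
               "shorter than the window")
})

test_that("noise-free end-to-end recovery of window MO2 is exact to 1e-6", {
  fish <- test_fish()
  phys <- phys_default()
  sim <- simulate_swim_trial(fish, phys, chamber_spec("swim"),
                             sensor = sensor_silent(), activity_cv = 0)
  ser <- process_trace(sim$trace, fish, chamber_spec("swim"))
  sm <- merge(as.data.frame(ser), sim$speed_map, by = "window_start")
  U0 <- 0.5
  m_true <- vapply(sm$speed_bl_s, function(U) {
    norm <- min(1, (U - U0) / (phys$ucrit_true_bl_s - U0))
    phys$smr_true + (phys$mmr_true - phys$smr_true) * norm^2
  }, numeric(1))
  expect_lt(max(abs(sm$mo2 - m_true) / m_true), 1e-6)
})

test_that("saturation audit flags windows dipping below 80% and reports minima", {
  fish <- test_fish()
  # heavy fish in a small chamber: large O2 drawdown
  heavy <- fish_record("h", "Sp", "BCF", 0.2, 0.15, body_volume_l = 0.2)
  phys <- phys_default(method_attenuation = c(swim = 1, chase = 1,
                                              circle = 0.8), epoc_tau_s = 1e12)
  sim <- simulate_chase_trial(heavy, phys, chamber_spec("chase"),
                              sensor = sensor_silent(), delay_s = 0,
                              duration_s = 960, activity_cv = 0)
  expect_true("below_80pct_saturation" %in% sim$trace$flags)
  ser <- process_trace(sim$trace, heavy, chamber_spec("chase"))
  expect_true(any(grepl("below_80pct_saturation", ser$flags)))
  expect_true(all(ser$saturation_min < 1))
})
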