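test_that("noise-free constant-rate windows are exact straight lines", {
  fish <- test_fish()
  # constant m: attenuation 1 with infinite EPOC tau gives m(t) = mmr
  phys <- phys_default(method_attenuation = c(swim = 1, chase = 1,
                                              circle = 0.8),
                       epoc_tau_s = 1e12)
  sim <- simulate_chase_trial(fish, phys, chamber_spec("chase"),
                              sensor = sensor_silent(), delay_s = 0,
                              duration_s = 1920, activity_cv = 0)
  d <- sim$trace$data
  w <- d[d$time_s < 300, ]
  fitted <- stats::lm(o2 ~ time_s, data = w)
  expect_lt(max(abs(stats::resid(fitted))), 1e-10)
  v_resp <- chamber_spec("chase")$volume_l - fish$body_volume_l
  expect_equal(unname(-stats::coef(fitted)[2]),
               phys$mmr_true * fish$mass_kg / 3600 / v_resp,
               tolerance = 1e-9)
})

test_that("swim trial realizes Brett's interpolation exactly", {
  fish <- test_fish()
  phys <- phys_default(ucrit_true_bl_s = 10.3)
  sim <- simulate_swim_trial(fish, phys, chamber_spec("swim"),
                             sensor = sensor_silent(), activity_cv = 0)
  fat <- attr(sim$ground_truth, "fatigue")
  # 13 fully completed speeds (4.0 .. 10.0), failure during the 14th
  expect_equal(fat$U_last, 10.0)
  expect_equal(fat$U_fail, 10.5)
  expect_equal(ucrit(fat$U_last, fat$U_i, fat$t_fail, fat$t_i), 10.3)
  comp <- sim$speed_map[sim$speed_map$cycle_complete, ]
  expect_equal(length(unique(comp$speed_bl_s[comp$speed_bl_s >= 4 &
                                               comp$speed_bl_s <= 10])), 13)
  # the trial-derived inputs reproduce the true Ucrit end to end
  ui <- ucrit_inputs_from_trial(sim$speed_map, sim$trace)
  expect_equal(ucrit(ui$U, ui$U_i, ui$t, ui$t_i), 10.3, tolerance = 1e-9)
})

test_that("simulation is deterministic under a fixed seed", {
  fish <- test_fish()
  phys <- phys_default()
  a <- simulate_swim_trial(fish, phys, chamber_spec("swim"), seed = 11)
  b <- simulate_swim_trial(fish, phys, chamber_spec("swim"), seed = 11)
  c <- simulate_swim_trial(fish, phys, chamber_spec("swim"), seed = 12)
  expect_identical(a$trace$data, b$trace$data)
  expect_false(identical(a$trace$data$o2, c$trace$data$o2))
})

test_that("chase trial expresses the attenuated EPOC peak and delay lowers it", {
  fish <- test_fish()
  ch <- chamber_spec("chase")
  # attenuation 1, tau -> inf, no noise: first-window MO2 equals mmr_true
  p1 <- phys_default(method_attenuation = c(swim = 1, chase = 1,
                                            circle = 0.8), epoc_tau_s = 1e12)
  s1 <- simulate_chase_trial(fish, p1, ch, sensor = sensor_silent(),
                             delay_s = 0, duration_s = 1920, activity_cv = 0)
  ser <- process_trace(s1$trace, fish, ch)
  expect_equal(ser$mo2[1], p1$mmr_true, tolerance = 1e-6)

  # attenuation 0.8: peak excess over the first window matches the
  # closed-form window mean of the exponential
  p2 <- phys_default(method_attenuation = c(swim = 1, chase = 0.8,
                                            circle = 0.7), epoc_tau_s = 1200)
  s2 <- simulate_chase_trial(fish, p2, ch, sensor = sensor_silent(),
                             delay_s = 0, duration_s = 1920, activity_cv = 0)
  m2 <- mmr_postexercise(s2$trace, "chase", fish, ch)
  A <- 0.8 * (p2$mmr_true - p2$smr_true)
  tau <- 1200
  expected_peak <- p2$smr_true + A * tau / 60 * (1 - exp(-60 / tau))
  expect_equal(m2$mmr, expected_peak, tolerance = 1e-3)
  expect_equal((expected_peak - p2$smr_true) / A, 0.975, tolerance = 1e-2)

  # handling delay strictly lowers the recovered peak (tau = 120 s)
  p3 <- phys_default(epoc_tau_s = 120)
  s_del <- simulate_chase_trial(fish, p3, ch, sensor = sensor_silent(),
                                delay_s = 10, duration_s = 1920,
                                activity_cv = 0)
  s_nodel <- simulate_chase_trial(fish, p3, ch, sensor = sensor_silent(),
                                  delay_s = 0, duration_s = 1920,
                                  activity_cv = 0)
  m_del <- mmr_postexercise(s_del$trace, "chase", fish, ch)
  m_nodel <- mmr_postexercise(s_nodel$trace, "chase", fish, ch)
  expect_lt(m_del$mmr, m_nodel$mmr)
})

test_that("circle trial plateau is recovered after the ramp and ordering holds", {
  fish <- test_fish()
  ci <- chamber_spec("circle")
  phys <- phys_default(method_attenuation = c(swim = 1, chase = 0.81,
                                              circle = 0.77))
  sim <- simulate_circle_trial(fish, phys, ci, sensor = sensor_silent(),
                               exercise_s = 360, activity_cv = 0)
  m <- mmr_postexercise(sim$trace, "circle", fish, ci, span = c(0, 300))
  target <- phys$smr_true + 0.77 * (phys$mmr_true - phys$smr_true)
  expect_gte(m$window_start, 60)     # steepest window after the 60 s ramp
  expect_equal(m$mmr, target, tolerance = 1e-6)

  # circle attenuation below chase attenuation preserves estimate order
  simc <- simulate_chase_trial(fish, phys, chamber_spec("chase"),
                               sensor = sensor_silent(), delay_s = 0,
                               duration_s = 1920, activity_cv = 0)
  mc <- mmr_postexercise(simc$trace, "chase", fish, chamber_spec("chase"))
  expect_lt(m$mmr, mc$mmr)
})

test_that("mass balance holds to 1e-9 for noise-free windows with background", {
  fish <- test_fish()
  sens <- sensor_model(noise_sd = 0, background_rate_0 = 0.08,
                       background_slope = 0.01)
  phys <- phys_default(method_attenuation = c(swim = 1, chase = 1,
                                              circle = 0.8), epoc_tau_s = 1e12)
  sim <- simulate_chase_trial(fish, phys, chamber_spec("chase"),
                              sensor = sens, delay_s = 0, duration_s = 1920,
                              activity_cv = 0)
  d <- sim$trace$data
  v_resp <- chamber_spec("chase")$volume_l - fish$body_volume_l
  for (w0 in c(0, 480, 960)) {
    iw <- d$time_s >= w0 & d$time_s < w0 + 300
    t0 <- min(d$time_s[iw]); t1 <- max(d$time_s[iw])
    drop <- d$o2[d$time_s == t0] - d$o2[d$time_s == t1]
    # independent integral: constant m plus linear background
    int_m <- phys$mmr_true * fish$mass_kg * (t1 - t0)
    int_b <- 0.08 * (t1 - t0) + 0.01 * (t1^2 - t0^2) / (2 * 3600)
    expect_equal(drop, (int_m + int_b) / 3600 / v_resp, tolerance = 1e-9)
  }
})

test_that("flush restores saturation; exponential flush approaches it monotonically", {
  fish <- test_fish()
  phys <- phys_default()
  s_i <- simulate_chase_trial(fish, phys, chamber_spec("chase"),
                              sensor = sensor_silent(), delay_s = 0,
                              duration_s = 1920, activity_cv = 0)
  d <- s_i$trace$data
  expect_true(all(d$o2[d$phase == "flush"] == s_i$trace$sat_conc))

  sens_e <- sensor_model(noise_sd = 0, background_rate_0 = 0,
                         background_slope = 0, flush_mode = "exponential",
                         flush_rate = 0.02)
  s_e <- simulate_chase_trial(fish, phys, chamber_spec("chase"),
                              sensor = sens_e, delay_s = 0,
                              duration_s = 1920, activity_cv = 0)
  de <- s_e$trace$data
  fl <- de[de$time_s >= 300 & de$time_s < 480, "o2"]
  expect_true(all(diff(fl) > 0))
  expect_true(all(fl < s_e$trace$sat_conc))
})

test_that("cohort simulation supports masking, degenerate designs and mean ordering", {
  des <- default_cohort_design(n_per_species = 2)[1, , drop = FALSE]
  des$between_cv <- 0; des$mass_cv <- 0; des$ucrit_cv <- 0
  co <- simulate_cohort(des, sensor_silent(), seed = 3,
                        resting_duration_s = 4800, habituation_s = 480)
  gt <- co$ground_truth
  # zero between-fish SD: identical ground truth across fish
  for (m in unique(gt$method)) {
    g <- gt[gt$method == m, ]
    expect_equal(g$mmr[1], g$mmr[2])
    expect_equal(g$smr[1], g$smr[2])
  }
  # generative method-level ordering: swim > chase > circle
  mm <- tapply(gt$mmr, gt$method, mean)
  expect_gt(mm["swim"], mm["chase"])
  expect_gt(mm["chase"], mm["circle"])

  # masking removes the trial but the cohort still builds
  msk <- data.frame(fish_id = gt$fish_id[1], protocol = "circle")
  co2 <- simulate_cohort(des, sensor_silent(), seed = 3, mask = msk,
                         resting_duration_s = 4800, habituation_s = 480)
  expect_equal(nrow(co2$ground_truth), nrow(gt) - 1)
  expect_false(paste0(gt$fish_id[1], ".circle") %in% names(co2$traces))

  des$n <- 0
  expect_error(simulate_cohort(des), "n_per_species")
})
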