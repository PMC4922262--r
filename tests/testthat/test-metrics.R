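mk_series <- function(window_start, mo2) {
  out <- data.frame(window_start = window_start,
                    window_end = window_start + 300, mo2 = mo2, r2 = 1,
                    background_fraction = 0, saturation_min = 0.95,
                    flags = "")
  class(out) <- c("mo2_series", "data.frame")
  out
}

test_that("swim MMR picks the top speed with a completed cycle", {
  ser <- mk_series(c(0, 480, 960, 1440), c(500, 510, 505, 620))
  sm <- data.frame(window_start = c(0, 480, 960, 1440),
                   speed_bl_s = c(4, 4, 4, 4.5),
                   cycle_complete = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(mmr_swim(ser, sm)$mmr, 620)

  # single speed, single cycle
  expect_equal(mmr_swim(mk_series(0, 777),
                        data.frame(window_start = 0, speed_bl_s = 4,
                                   cycle_complete = TRUE))$mmr, 777)

  # failure during the first cycle of the top speed falls back
  sm$cycle_complete[4] <- FALSE
  expect_equal(mmr_swim(ser, sm)$mmr, 510)
  expect_equal(mmr_swim(ser, sm)$speed_bl_s, 4)
  expect_equal(mmr_swim(ser, sm, statistic = "mean")$mmr, mean(c(500, 510, 505)))

  sm$cycle_complete <- FALSE
  expect_error(mmr_swim(ser, sm), "completed full cycle|completed")
})

test_that("post-exercise MMR of a pure-background trace floors at zero with a flag", {
  fish <- test_fish()
  ch <- chamber_spec("chase")
  tt <- seq(0, 298, by = 2)
  # background-only decline, fully attributed to the background model
  bg_rate <- 0.36  # mg/h
  v_resp <- ch$volume_l - fish$body_volume_l
  o2 <- 6.2 - (bg_rate / 3600 / v_resp) * tt
  tr <- oxygen_trace("bg", "chase", tt, o2, phase = rep("measure", 150))
  bg <- background_model(bg_rate, bg_rate, 0, 600)
  m <- mmr_postexercise(tr, "chase", fish, ch, background = bg)
  expect_equal(m$mmr, 0, tolerance = 1e-9)
  expect_match(m$flags, "background_overcorrection")
})

test_that("lowest-fraction SMR follows the ceiling rule and its invariances", {
  ser <- mk_series(21600 + 480 * (0:9), 1:10)
  expect_equal(smr_lowest_fraction(ser)$smr, 1)
  expect_equal(smr_lowest_fraction(ser)$k, 1)

  ser25 <- mk_series(21600 + 480 * (0:24), 1:25)
  got <- smr_lowest_fraction(ser25)
  expect_equal(got$k, 3)
  expect_equal(got$smr, 2)          # mean(1, 2, 3)

  serc <- mk_series(21600 + 480 * (0:14), rep(137.5, 15))
  expect_equal(smr_lowest_fraction(serc, fraction = 0.10)$smr, 137.5)
  expect_equal(smr_lowest_fraction(serc, fraction = 0.5)$smr, 137.5)

  # adding a value >= the current maximum never changes the estimate
  ser26 <- mk_series(21600 + 480 * (0:25), c(1:25, 99))
  expect_equal(smr_lowest_fraction(ser26)$smr,
               smr_lowest_fraction(ser25)$smr)

  # windows before the recovery cutoff are excluded
  ser_pre <- mk_series(c(0, 21600 + 480 * (0:9)), c(0.01, 1:10))
  expect_equal(smr_lowest_fraction(ser_pre)$smr, 1)

  expect_error(smr_lowest_fraction(mk_series(21600 + 480 * (0:5), 1:6)),
               ">= 10")
})

test_that("SMR estimate decreases with sensor noise (documented selection bias)", {
  fish <- test_fish()
  ch <- chamber_spec("chase")
  phys <- phys_default(method_attenuation = c(swim = 1, chase = 1,
                                              circle = 0.8), epoc_tau_s = 1)
  est_at_noise <- function(sd, seeds) {
    vapply(seeds, function(s) {
      sens <- sensor_model(noise_sd = sd, background_rate_0 = 0,
                           background_slope = 0)
      sim <- simulate_chase_trial(fish, phys, ch, sensor = sens, seed = s,
                                  delay_s = 0, duration_s = 12000,
                                  activity_cv = 0)
      ser <- process_trace(sim$trace, fish, ch)
      smr_lowest_fraction(ser, recovery_cutoff_s = 4800)$smr
    }, numeric(1))
  }
  seeds <- 1:6
  lo <- mean(est_at_noise(0.002, seeds))
  hi <- mean(est_at_noise(0.02, seeds))
  expect_lt(hi, lo)
})

test_that("zero-speed extrapolation recovers the generative intercept", {
  ser <- mk_series(480 * (0:20), NA)
  U <- rep(seq(4, 10, length.out = 7), 3)
  ser$mo2 <- 150 + 2 * U^2
  sm <- data.frame(window_start = ser$window_start, speed_bl_s = U,
                   cycle_complete = TRUE)
  fit <- smr_extrapolate(ser, sm)
  expect_equal(fit$smr, 150, tolerance = 1e-4)
  expect_equal(fit$c, 2, tolerance = 1e-3)
  expect_equal(fit$smr_source, "extrapolated")

  withr::local_seed(9)
  sern <- ser
  sern$mo2 <- (150 + 2 * U^2) * exp(stats::rnorm(21, 0, 0.05))
  fitn <- smr_extrapolate(sern, sm)
  expect_lt(abs(fitn$smr - 150) / 150, 0.25)

  two <- mk_series(c(0, 480), c(100, 200))
  sm2 <- data.frame(window_start = c(0, 480), speed_bl_s = c(4, 6),
                    cycle_complete = TRUE)
  expect_error(smr_extrapolate(two, sm2), ">= 3 distinct speeds")
})

test_that("Ucrit boundaries and interpolation match hand arithmetic", {
  expect_equal(ucrit(10, 0.5, 0, 1440), 10)
  expect_equal(ucrit(10, 0.5, 1440, 1440), 10.5)
  expect_equal(ucrit(10.0, 0.5, 720, 1440), 10.25)
  # linear in t and bounded
  ts <- seq(0, 1440, by = 90)
  vals <- vapply(ts, function(t) ucrit(8, 0.5, t, 1440), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 8 & vals <= 8.5))
  expect_equal(diff(vals), rep(0.5 * 90 / 1440, length(ts) - 1))
  expect_error(ucrit(10, 0.5, 1500, 1440), "exceeds t_i")
})

test_that("solid-blocking correction follows the 3/2-power law with the 5% alert", {
  expect_equal(as.numeric(blocking_correction(50, 0, 0.0049)), 50)

  # epsilon exactly 0.05 is accepted without warning (boundary inclusive)
  a_ratio <- 0.0625^(2 / 3)
  expect_no_warning(v <- blocking_correction(100, a_ratio, 1))
  expect_equal(attr(v, "epsilon"), 0.05, tolerance = 1e-12)
  expect_equal(as.numeric(v), 105, tolerance = 1e-9)

  expect_warning(w <- blocking_correction(60, 0.25, 1), "exceeds 5%")
  expect_equal(attr(w, "epsilon"), 0.8 * 0.25^1.5)  # = 0.1
  expect_equal(as.numeric(w), 66, tolerance = 1e-9)

  expect_error(blocking_correction(60, 0.01, -1), "positive")
  expect_error(blocking_correction(60, 2, 1), "smaller than the tunnel")
})

test_that("aerobic scope is MMR minus SMR with flagged negatives", {
  expect_equal(as.numeric(aerobic_scope(1794.3, 223.3)), 1571.0)
  expect_equal(as.numeric(aerobic_scope(500, 500)), 0)
  expect_warning(s <- aerobic_scope(200, 300), "negative aerobic scope")
  expect_true(attr(s, "flagged_negative"))
  expect_equal(as.numeric(s), -100)
})
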