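#' Ground-truth fish physiology for simulation
#'
#' Parameters of the generative metabolic model. During swimming, metabolic
#' rate follows a drag-power-type curve
#' `m(U) = smr + a * (mmr - smr) * ((U - U0) / (Ucrit - U0))^c`, capped at
#' the method-expressed maximum. After exhaustive exercise, excess
#' post-exercise oxygen consumption (EPOC) decays as a single exponential
#' with time constant `epoc_tau_s`.
#'
#' `method_attenuation` encodes how much of the full aerobic span
#' (mmr - smr) each protocol expresses as peak excess MO2: short protocols
#' that force an immediate burst gait under-express the maximum.
#'
#' @param smr_true Standard metabolic rate (mg O2 kg^-1 h^-1).
#' @param mmr_true Maximal metabolic rate (mg O2 kg^-1 h^-1), > `smr_true`.
#' @param ucrit_true_bl_s True critical swimming speed (BL s^-1).
#' @param speed_exponent_c Exponent of the metabolic power curve, >= 1
#'   (default 2, hydrodynamic drag-power heritage).
#' @param epoc_tau_s EPOC decay time constant (s).
#' @param method_attenuation Named fractions in (0, 1] for `swim`, `chase`,
#'   `circle`.
#' @return An object of class `fish_physiology`.
#' @export
fish_physiology <- function(smr_true = 200, mmr_true = 1600,
                            ucrit_true_bl_s = 10.3, speed_exponent_c = 2,
                            epoc_tau_s = 1200,
                            method_attenuation = c(swim = 1, chase = 0.81,
                                                   circle = 0.77)) {
  stopifnot(smr_true > 0, mmr_true > smr_true, speed_exponent_c >= 1,
            epoc_tau_s > 0, all(method_attenuation > 0),
            all(method_attenuation <= 1))
  stopifnot(all(c("swim", "chase", "circle") %in% names(method_attenuation)))
  structure(list(smr_true = smr_true, mmr_true = mmr_true,
                 ucrit_true_bl_s = ucrit_true_bl_s,
                 speed_exponent_c = speed_exponent_c,
                 epoc_tau_s = epoc_tau_s,
                 method_attenuation = method_attenuation),
            class = "fish_physiology")
}

#' Sensor and chamber-nuisance model
#'
#' @param noise_sd Gaussian i.i.d. sensor noise per sample (mg O2 L^-1);
#'   the default matches the resolution scale of optical O2 meters.
#' @param background_rate_0 Whole-chamber microbial O2 uptake at trial start
#'   (mg O2 h^-1).
#' @param background_slope Linear drift of the background rate
#'   (mg O2 h^-1 per hour).
#' @param flush_mode `"instant"` (flush restores exactly full saturation) or
#'   `"exponential"` (saturation approached monotonically at `flush_rate`).
#' @param flush_rate Washout rate constant (s^-1) for exponential flushing.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(noise_sd = 0.005, background_rate_0 = 0.05,
                         background_slope = 0.005,
                         flush_mode = c("instant", "exponential"),
                         flush_rate = 0.05) {
  flush_mode <- match.arg(flush_mode)
  stopifnot(noise_sd >= 0, background_rate_0 >= 0, flush_rate > 0)
  structure(list(noise_sd = noise_sd, background_rate_0 = background_rate_0,
                 background_slope = background_slope, flush_mode = flush_mode,
                 flush_rate = flush_rate),
            class = "sensor_model")
}

## ---- exact metabolic-rate profile integrals -------------------------------
## m(t) is piecewise {constant, linear ramp, exponential decay}; integrals
## are closed-form so simulated O2 drops satisfy mass balance to machine
## precision (the within-window decline is linear whenever m is constant,
## matching the linear-regression slope estimator downstream).

m_piece_const <- function(t0, t1, v) {
  force(v)  # closures are built in loops: capture values, not promises
  list(t0 = t0, t1 = t1, f = function(a, b) v * (b - a))
}
m_piece_linear <- function(t0, t1, v0, v1) {
  force(v0)
  slope <- (v1 - v0) / (t1 - t0)
  list(t0 = t0, t1 = t1, f = function(a, b) {
    v0 * (b - a) + slope * ((b - t0)^2 - (a - t0)^2) / 2
  })
}
m_piece_exp <- function(t0, t1, base, A, tau, tref) {
  force(base); force(A); force(tau); force(tref)
  ## exp(-a/tau) - exp(-b/tau) via expm1 to stay exact when tau >> b - a
  list(t0 = t0, t1 = t1, f = function(a, b) {
    base * (b - a) -
      A * tau * exp(-(a - tref) / tau) * expm1(-(b - a) / tau)
  })
}

## integral of m over [a, b] (units: (mg O2 kg^-1 h^-1) * s)
int_profile <- function(pieces, a, b) {
  tot <- 0
  for (p in pieces) {
    lo <- max(a, p$t0); hi <- min(b, p$t1)
    if (hi > lo) tot <- tot + p$f(lo, hi)
  }
  tot
}

## integral of background rate over [a, b] (units: (mg O2 h^-1) * s)
int_background <- function(sensor, a, b) {
  sensor$background_rate_0 * (b - a) +
    sensor$background_slope * (b^2 - a^2) / (2 * 3600)
}

## ---- generic trace assembly -----------------------------------------------
## plan: data.frame(start, end, phase, sealed, m_extra); pieces: m profile.
## Returns list(trace, min_sat): samples on a fixed 2 s grid, O2 computed
## from the exact uptake integral within sealed segments and the flush model
## otherwise.
build_trace <- function(plan, pieces, fish, chamber, sensor, sat, dt = 2) {
  v_resp <- chamber$volume_l - fish$body_volume_l
  if (v_resp <= 0)
    stop(sprintf("fish '%s' does not fit chamber (%g L): non-positive effective volume",
                 fish$fish_id, chamber$volume_l))
  t_end <- plan$end[nrow(plan)]
  times <- seq(0, t_end - dt / 2, by = dt)
  o2 <- numeric(length(times))
  phase <- character(length(times))
  C <- sat
  min_sealed <- Inf
  for (i in seq_len(nrow(plan))) {
    idx <- which(times >= plan$start[i] & times < plan$end[i])
    tt <- times[idx]
    if (plan$sealed[i]) {
      upt <- vapply(tt, function(t) {
        (fish$mass_kg * (int_profile(pieces, plan$start[i], t) +
                           plan$m_extra[i] * (t - plan$start[i])) +
           int_background(sensor, plan$start[i], t)) / 3600
      }, numeric(1))
      o2[idx] <- C - upt / v_resp
      C_end <- C - (fish$mass_kg * (int_profile(pieces, plan$start[i], plan$end[i]) +
                                      plan$m_extra[i] * (plan$end[i] - plan$start[i])) +
                      int_background(sensor, plan$start[i], plan$end[i])) /
        3600 / v_resp
      if (length(idx)) min_sealed <- min(min_sealed, min(o2[idx]), C_end)
      C <- C_end
    } else if (sensor$flush_mode == "instant" ||
                 plan$phase[i] %in% c("ramp", "habituation")) {
      o2[idx] <- sat
      C <- sat
    } else {
      o2[idx] <- sat - (sat - C) * exp(-sensor$flush_rate * (tt - plan$start[i]))
      C <- sat - (sat - C) * exp(-sensor$flush_rate * (plan$end[i] - plan$start[i]))
    }
    phase[idx] <- plan$phase[i]
  }
  if (sensor$noise_sd > 0) o2 <- o2 + stats::rnorm(length(o2), 0, sensor$noise_sd)
  o2 <- pmax(o2, 1e-6)
  list(times = times, o2 = o2, phase = phase, min_sealed = min_sealed,
       v_resp = v_resp)
}

## measure/flush cycle plan rows covering [t0, t0 + n_cycles * cycle_len)
cycle_plan <- function(t0, n_cycles, cycles, m_extra = 0) {
  starts <- t0 + (seq_len(n_cycles) - 1) * cycle_len(cycles)
  do.call(rbind, lapply(starts, function(s) {
    data.frame(start = c(s, s + cycles$measure_s),
               end = c(s + cycles$measure_s, s + cycle_len(cycles)),
               phase = c("measure", "flush"), sealed = c(TRUE, FALSE),
               m_extra = m_extra)
  }))
}

## per-window positive activity excess above SMR (biological, not sensor)
activity_draw <- function(n, smr, activity_cv) {
  if (activity_cv <= 0) return(rep(0, n))
  abs(stats::rnorm(n, 0, activity_cv * smr))
}

finish_trace <- function(built, fish, protocol, sat) {
  tr <- oxygen_trace(fish$fish_id, protocol, built$times, built$o2,
                     phase = built$phase, sat_conc = sat)
  if (is.finite(built$min_sealed) && built$min_sealed < 0.8 * sat)
    tr$flags <- c(tr$flags, "below_80pct_saturation")
  tr
}

## true background rates at trial start/end, for the correction stage
true_background <- function(sensor, t_end) {
  background_model(rate_pre = sensor$background_rate_0,
                   rate_post = sensor$background_rate_0 +
                     sensor$background_slope * t_end / 3600,
                   t_pre = 0, t_post = t_end)
}

#' Simulate an incremental swim trial (Ucrit protocol)
#'
#' Habituation cycles at a low speed, a ramp, then stepped speed increments
#' with `cycles_per_speed` measure/flush cycles each. Metabolic rate follows
#' the power curve of [fish_physiology()]; the fish fatigues partway into
#' the increment containing its true Ucrit, at the time that makes Brett's
#' interpolation recover `ucrit_true_bl_s` exactly.
#'
#' @param fish A [fish_record()].
#' @param phys A [fish_physiology()].
#' @param chamber A [chamber_spec()] with `protocol == "swim"`.
#' @param schedule A [swim_schedule()].
#' @param cycles A [cycle_schedule()].
#' @param sensor A [sensor_model()].
#' @param seed Integer seed (NULL to use the current RNG state).
#' @param habituation_s Habituation duration (s), rounded down to whole
#'   cycles.
#' @param activity_cv Spontaneous-activity coefficient of variation: each
#'   measurement window receives a positive excess `|N(0, cv * smr)|`.
#' @param sat Full-saturation O2 concentration (mg L^-1).
#' @return A list with `trace` (an [oxygen_trace()]), `ground_truth` (a
#'   [metabolic_summary()] carrying the generative values, with fatigue
#'   details as attributes), `speed_map` (data frame mapping measurement
#'   windows to speeds and cycle-completion status) and `background` (the
#'   true [background_model()]).
#' @export
simulate_swim_trial <- function(fish, phys, chamber, schedule = swim_schedule(),
                                cycles = cycle_schedule(),
                                sensor = sensor_model(), seed = NULL,
                                habituation_s = 1920, activity_cv = 0.03,
                                sat = sat_conc_default) {
  stopifnot(chamber$protocol == "swim")
  if (!is.null(seed)) set.seed(seed)
  U0 <- schedule$habituation_speed_bl_s
  Ui <- schedule$increment_bl_s
  ti <- schedule$time_per_speed_s
  ucrit <- phys$ucrit_true_bl_s
  if (ucrit <= schedule$start_speed_bl_s)
    stop("ucrit_true_bl_s must exceed the start speed")
  att <- phys$method_attenuation[["swim"]]
  span <- phys$mmr_true - phys$smr_true
  m_at <- function(U) {
    norm <- max(0, (U - U0) / (ucrit - U0))
    phys$smr_true + att * span * min(1, norm)^phys$speed_exponent_c
  }

  ## fully completed speeds, then fatigue t_fail into the next increment
  k_last <- ceiling((ucrit - schedule$start_speed_bl_s) / Ui) - 1L
  U_last <- schedule$start_speed_bl_s + k_last * Ui
  U_fail <- U_last + Ui
  t_fail <- (ucrit - U_last) / Ui * ti

  n_hab <- max(1L, floor(habituation_s / cycle_len(cycles)))
  hab_end <- n_hab * cycle_len(cycles)
  ramp_end <- hab_end + schedule$ramp_s

  plan <- data.frame(start = numeric(0), end = numeric(0),
                     phase = character(0), sealed = logical(0),
                     m_extra = numeric(0))
  pieces <- list()
  sm <- data.frame(window_start = numeric(0), window_end = numeric(0),
                   speed_bl_s = numeric(0), cycle_complete = logical(0))

  hab <- cycle_plan(0, n_hab, cycles)
  hab$phase <- "habituation"   # habituation cycles excluded from estimation
  plan <- rbind(plan, hab,
                data.frame(start = hab_end, end = ramp_end, phase = "ramp",
                           sealed = FALSE, m_extra = 0))
  pieces <- c(pieces, list(m_piece_const(0, ramp_end, m_at(U0))))

  t0 <- ramp_end
  speeds <- seq(schedule$start_speed_bl_s, U_fail, by = Ui)
  for (U in speeds) {
    final <- (U == U_fail)
    dur <- if (final) t_fail else ti
    n_full <- floor(dur / cycle_len(cycles))
    if (n_full > 0) {
      cp <- cycle_plan(t0, n_full, cycles)
      for (j in seq_len(n_full)) {
        ws <- t0 + (j - 1) * cycle_len(cycles)
        act <- activity_draw(1, phys$smr_true, activity_cv)
        cp$m_extra[2 * j - 1] <- act
        sm <- rbind(sm, data.frame(window_start = ws,
                                   window_end = ws + cycles$measure_s,
                                   speed_bl_s = U, cycle_complete = TRUE))
      }
      plan <- rbind(plan, cp)
    }
    rem <- dur - n_full * cycle_len(cycles)
    if (final && rem > 0) {
      s <- t0 + n_full * cycle_len(cycles)
      m_end <- min(rem, cycles$measure_s)
      act <- activity_draw(1, phys$smr_true, activity_cv)
      plan <- rbind(plan, data.frame(start = s, end = s + m_end,
                                     phase = "measure", sealed = TRUE,
                                     m_extra = act))
      if (rem > cycles$measure_s)
        plan <- rbind(plan, data.frame(start = s + cycles$measure_s,
                                       end = s + rem, phase = "flush",
                                       sealed = FALSE, m_extra = 0))
      sm <- rbind(sm, data.frame(window_start = s, window_end = s + m_end,
                                 speed_bl_s = U, cycle_complete = FALSE))
    }
    pieces <- c(pieces, list(m_piece_const(t0, t0 + dur, m_at(U))))
    t0 <- t0 + dur
  }

  built <- build_trace(plan, pieces, fish, chamber, sensor, sat)
  trace <- finish_trace(built, fish, "swim", sat)
  sl_cm <- fish$standard_length_m * 100
  gt <- metabolic_summary(fish$fish_id, fish$species, fish$swim_mode,
                          method = "swim",
                          mmr = phys$smr_true + att * span, smr = phys$smr_true,
                          aerobic_scope = phys$mmr_true - phys$smr_true,
                          ucrit_abs_cm_s = ucrit * sl_cm,
                          ucrit_rel_bl_s = ucrit)
  attr(gt, "mmr_true") <- phys$mmr_true
  attr(gt, "fatigue") <- list(U_last = U_last, U_fail = U_fail,
                              t_fail = t_fail, t_i = ti, U_i = Ui)
  list(trace = trace, ground_truth = gt, speed_map = sm,
       background = true_background(sensor, plan$end[nrow(plan)]))
}

#' Simulate an exhaustive-chase trial with resting respirometry
#'
#' The fish is chased to exhaustion and air-exposed outside the chamber;
#' the trace starts at the post-exercise measurement onset, `delay_s`
#' seconds after exercise ended. MO2 decays from the method-expressed peak
#' as `smr + A exp(-t / tau)` with `A = attenuation_chase * (mmr - smr)`,
#' through repeated measure/flush cycles long enough for the SMR tail.
#'
#' @inheritParams simulate_swim_trial
#' @param delay_s Handling time between end of exercise and measurement
#'   onset (s, in `[0, 10]`).
#' @param duration_s Total trial duration (s); default 8 h so that at least
#'   10 windows follow a 6 h recovery cutoff.
#' @return As [simulate_swim_trial()], without `speed_map`.
#' @export
simulate_chase_trial <- function(fish, phys, chamber,
                                 cycles = cycle_schedule(),
                                 sensor = sensor_model(), delay_s = 10,
                                 seed = NULL, duration_s = 28800,
                                 activity_cv = 0.03, sat = sat_conc_default) {
  stopifnot(chamber$protocol %in% c("rest", "chase"),
            delay_s >= 0, delay_s <= 10)
  if (!is.null(seed)) set.seed(seed)
  A <- phys$method_attenuation[["chase"]] * (phys$mmr_true - phys$smr_true)
  n_cycles <- floor(duration_s / cycle_len(cycles))
  plan <- cycle_plan(0, n_cycles, cycles)
  meas <- plan$phase == "measure"
  plan$m_extra[meas] <- activity_draw(sum(meas), phys$smr_true, activity_cv)
  pieces <- list(m_piece_exp(0, n_cycles * cycle_len(cycles), phys$smr_true,
                             A, phys$epoc_tau_s, tref = -delay_s))
  built <- build_trace(plan, pieces, fish, chamber, sensor, sat)
  trace <- finish_trace(built, fish, "chase", sat)
  gt <- metabolic_summary(fish$fish_id, fish$species, fish$swim_mode,
                          method = "chase",
                          mmr = phys$smr_true + A, smr = phys$smr_true,
                          aerobic_scope = phys$mmr_true - phys$smr_true)
  attr(gt, "mmr_true") <- phys$mmr_true
  list(trace = trace, ground_truth = gt,
       background = true_background(sensor, plan$end[nrow(plan)]))
}

#' Simulate a circular-chamber trial
#'
#' Measurement is continuous during exercise (no flushing is possible until
#' the fish fatigues): stir-bar speed ramps over ~1 min to the maximum the
#' fish can hold, MO2 ramps with it to
#' `smr + attenuation_circle * (mmr - smr)` and holds until `exercise_s`.
#' The chamber is then flushed and resting cycles follow (EPOC decays, then
#' the SMR tail).
#'
#' @inheritParams simulate_chase_trial
#' @param exercise_s Continuous exercise/measurement duration (s), in
#'   `[300, 420]` (5-7 min).
#' @param ramp_s Exercise ramp-up duration (s).
#' @export
simulate_circle_trial <- function(fish, phys, chamber,
                                  cycles = cycle_schedule(),
                                  sensor = sensor_model(), exercise_s = 360,
                                  seed = NULL, duration_s = 28800,
                                  ramp_s = 60, activity_cv = 0.03,
                                  sat = sat_conc_default) {
  stopifnot(chamber$protocol == "circle",
            exercise_s >= 300, exercise_s <= 420, ramp_s < exercise_s)
  if (!is.null(seed)) set.seed(seed)
  A <- phys$method_attenuation[["circle"]] * (phys$mmr_true - phys$smr_true)
  plateau <- phys$smr_true + A
  flush_end <- exercise_s + cycles$flush_s
  n_rest <- floor((duration_s - flush_end) / cycle_len(cycles))
  plan <- rbind(
    data.frame(start = 0, end = exercise_s, phase = "measure", sealed = TRUE,
               m_extra = 0),
    data.frame(start = exercise_s, end = flush_end, phase = "flush",
               sealed = FALSE, m_extra = 0),
    cycle_plan(flush_end, n_rest, cycles))
  meas <- plan$phase == "measure" & plan$start >= flush_end
  plan$m_extra[meas] <- activity_draw(sum(meas), phys$smr_true, activity_cv)
  pieces <- list(
    m_piece_linear(0, ramp_s, phys$smr_true, plateau),
    m_piece_const(ramp_s, exercise_s, plateau),
    m_piece_exp(exercise_s, plan$end[nrow(plan)], phys$smr_true, A,
                phys$epoc_tau_s, tref = exercise_s))
  built <- build_trace(plan, pieces, fish, chamber, sensor, sat)
  trace <- finish_trace(built, fish, "circle", sat)
  gt <- metabolic_summary(fish$fish_id, fish$species, fish$swim_mode,
                          method = "circle", mmr = plateau,
                          smr = phys$smr_true,
                          aerobic_scope = phys$mmr_true - phys$smr_true)
  attr(gt, "mmr_true") <- phys$mmr_true
  list(trace = trace, ground_truth = gt,
       background = true_background(sensor, plan$end[nrow(plan)]))
}

#' Default cohort design: four coral-reef species, two swimming modes
#'
#' Representative species-level parameters for two body-caudal fin (BCF)
#' fusiliers and two median-paired fin (MPF) damselfishes of the Great
#' Barrier Reef, spanning the mass, SMR, MMR and Ucrit ranges typical of
#' small tropical steady swimmers. Chase and circle attenuations are
#' calibrated so that generative method-level MMR ratios are
#' 1 : 1/1.2 : 1/1.25 (swim : chase : circle), i.e. swim-tunnel MMR exceeds
#' chase and circle MMR by 20% and 25%.
#'
#' @param n_per_species Integer vector (recycled) of fish per species.
#' @return A data frame, one row per species, consumed by
#'   [simulate_cohort()].
#' @export
default_cohort_design <- function(n_per_species = c(5, 11, 11, 10)) {
  d <- data.frame(
    species = c("Pterocaesio marri", "Caesio teres",
                "Acanthochromis polyacanthus", "Chromis atripectoralis"),
    swim_mode = c("BCF", "BCF", "MPF", "MPF"),
    mass_mean_kg = c(0.00989, 0.01507, 0.01688, 0.00810),
    mass_cv = 0.15,
    sl_mean_m = c(0.0852, 0.0822, 0.0742, 0.0625),
    smr_mean = c(223.3, 167.7, 143.0, 221.0),
    mmr_mean = c(1794.3, 1299.4, 1150.7, 1768.0),
    ucrit_mean_bl_s = c(10.10, 10.13, 8.43, 12.10),
    between_cv = 0.20, ucrit_cv = 0.05,
    epoc_tau_s = 1200, speed_exponent_c = 2,
    stringsAsFactors = FALSE)
  d$n <- rep_len(n_per_species, nrow(d))
  ## attenuations hitting method ratios 1 : 1/1.2 : 1/1.25 exactly
  d$att_chase <- (d$mmr_mean / 1.2 - d$smr_mean) / (d$mmr_mean - d$smr_mean)
  d$att_circle <- (d$mmr_mean / 1.25 - d$smr_mean) / (d$mmr_mean - d$smr_mean)
  d
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a repeated-measures cohort across the three protocols
#'
#' Each fish draws one physiology (log-normal between-fish variation around
#' its species means, with SMR and MMR sharing a common fish-level factor)
#' and undergoes up to three simulated trials (swim, chase, circle) in
#' randomized order. Individual trials can be masked to emulate fish that
#' did not complete every method.
#'
#' @param design Per-species parameter table; see [default_cohort_design()].
#' @param sensor A [sensor_model()] shared across trials.
#' @param cycles A [cycle_schedule()].
#' @param seed Integer seed.
#' @param mask Optional data frame (`fish_id`, `protocol`) of trials to
#'   omit.
#' @param resting_duration_s Duration of chase/circle trials (s).
#' @param habituation_s Swim-trial habituation duration (s).
#' @param activity_cv Per-window spontaneous-activity CV.
#' @param chambers Named list of [chamber_spec()] for `swim`, `chase`,
#'   `circle` (defaults to the standard volumes).
#' @return A list: `traces` (named list of [oxygen_trace()]), `metadata`
#'   (fish table), `fish` (list of [fish_record()]), `ground_truth`
#'   (metabolic_summary table, one row per completed fish x method),
#'   `speed_maps` (named list, swim trials), `backgrounds` (named list of
#'   [background_model()]).
#' @export
simulate_cohort <- function(design = default_cohort_design(),
                            sensor = sensor_model(),
                            cycles = cycle_schedule(), seed = 1,
                            mask = NULL, resting_duration_s = 28800,
                            habituation_s = 1920, activity_cv = 0.03,
                            chambers = list(swim = chamber_spec("swim"),
                                            chase = chamber_spec("chase"),
                                            circle = chamber_spec("circle"))) {
  if (any(design$n < 1)) stop("n_per_species must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  traces <- list(); speed_maps <- list(); backgrounds <- list()
  gt <- NULL; meta <- NULL; fishes <- list()
  for (s in seq_len(nrow(design))) {
    row <- design[s, ]
    for (i in seq_len(row$n)) {
      id <- sprintf("%s_%02d", abbreviate(gsub(" ", "_", row$species), 8), i)
      mass <- row$mass_mean_kg * lognorm_factor(1, row$mass_cv)
      sl <- row$sl_mean_m * (mass / row$mass_mean_kg)^(1 / 3)
      f <- lognorm_factor(1, row$between_cv)  # shared SMR/MMR fish factor
      phys <- fish_physiology(
        smr_true = row$smr_mean * f, mmr_true = row$mmr_mean * f,
        ucrit_true_bl_s = row$ucrit_mean_bl_s * lognorm_factor(1, row$ucrit_cv),
        speed_exponent_c = row$speed_exponent_c, epoc_tau_s = row$epoc_tau_s,
        method_attenuation = c(swim = 1, chase = row$att_chase,
                               circle = row$att_circle))
      fish <- fish_record(id, row$species, row$swim_mode, mass_kg = mass,
                          standard_length_m = sl)
      fishes[[id]] <- fish
      order_i <- sample(c("swim", "chase", "circle"))
      meta <- rbind(meta, data.frame(
        fish_id = id, species = row$species, swim_mode = row$swim_mode,
        mass_kg = mass, standard_length_m = sl,
        trial_order = paste(order_i, collapse = ">"),
        stringsAsFactors = FALSE))
      for (proto in order_i) {
        if (!is.null(mask) &&
              any(mask$fish_id == id & mask$protocol == proto)) next
        sim <- switch(proto,
          swim = simulate_swim_trial(fish, phys, chambers$swim,
                                     cycles = cycles, sensor = sensor,
                                     habituation_s = habituation_s,
                                     activity_cv = activity_cv),
          chase = simulate_chase_trial(fish, phys, chambers$chase,
                                       cycles = cycles, sensor = sensor,
                                       duration_s = resting_duration_s,
                                       activity_cv = activity_cv),
          circle = simulate_circle_trial(fish, phys, chambers$circle,
                                         cycles = cycles, sensor = sensor,
                                         duration_s = resting_duration_s,
                                         activity_cv = activity_cv))
        key <- paste(id, proto, sep = ".")
        traces[[key]] <- sim$trace
        backgrounds[[key]] <- sim$background
        if (proto == "swim") speed_maps[[key]] <- sim$speed_map
        g <- sim$ground_truth
        g$mmr_true <- attr(g, "mmr_true")
        gt <- rbind(gt, as.data.frame(g))
      }
    }
  }
  rownames(gt) <- NULL
  list(traces = traces, metadata = meta, fish = fishes, ground_truth = gt,
       speed_maps = speed_maps, backgrounds = backgrounds)
}

#' Synthetic per-method reference summaries for four reef species
#'
#' Representative species-by-method group summaries (mean, SEM, n) for the
#' four species of [default_cohort_design()]: MMR under the three
#' protocols, SMR under the two resting protocols, and absolute/relative
#' Ucrit. These are synthetic calibration tables used to parameterize
#' stand-in cohorts for exercising the comparison stage; they are not
#' measurements made by this package.
#'
#' @return A list of data frames: `mmr`, `smr` (columns `species`,
#'   `swim_mode`, `method`, `mean`, `sem`, `n`) and `ucrit` (columns
#'   `species`, `swim_mode`, `mean_abs_cm_s`, `sem_abs`, `mean_rel_bl_s`,
#'   `sem_rel`, `n`).
#' @export
example_method_summaries <- function() {
  sp <- c("Pterocaesio marri", "Caesio teres",
          "Acanthochromis polyacanthus", "Chromis atripectoralis")
  mode <- c("BCF", "BCF", "MPF", "MPF")
  n <- c(5, 11, 11, 10)
  mmr <- data.frame(
    species = rep(sp, each = 3), swim_mode = rep(mode, each = 3),
    method = rep(c("swim", "chase", "circle"), 4),
    mean = c(1794.3, 1376.4, 1308.1,
             1299.4, 1277.9, 1175.8,
             1150.7, 1048.1, 974.4,
             1768.0, 1556.7, 1312.8),
    sem = c(336.6, 182.5, 254.8,
            59.4, 169.8, 102.5,
            112.3, 164.2, 80.4,
            112.2, 134.7, 104.5),
    n = rep(n, each = 3), stringsAsFactors = FALSE)
  smr <- data.frame(
    species = rep(sp, each = 2), swim_mode = rep(mode, each = 2),
    method = rep(c("chase", "circle"), 4),
    mean = c(223.3, 257.9, 167.7, 176.5, 143.0, 145.1, 221.0, 154.5),
    sem = c(40.3, 24.6, 31.3, 17.5, 26.1, 7.2, 35.9, 10.2),
    n = rep(n, each = 2), stringsAsFactors = FALSE)
  ucrit <- data.frame(
    species = sp, swim_mode = mode,
    mean_abs_cm_s = c(82.05, 83.96, 63.12, 75.57),
    sem_abs = c(5.10, 3.20, 1.76, 3.41),
    mean_rel_bl_s = c(10.10, 10.13, 8.43, 12.10),
    sem_rel = c(1.04, 0.30, 0.19, 0.50),
    n = n, stringsAsFactors = FALSE)
  list(mmr = mmr, smr = smr, ucrit = ucrit)
}

#' Simulate a stand-in cohort from per-cell group summaries
#'
#' Draws one value per fish x method from cell means and SDs
#' (`sd = sem * sqrt(n)`), with part of each cell's variance assigned to a
#' shared per-fish factor (repeated-measures structure) and the rest to
#' residual noise. Used to exercise the comparison stage against known
#' group-level structure.
#'
#' @param cells Data frame with columns `species`, `swim_mode`, `method`,
#'   `mean`, `sem`, `n`.
#' @param fish_share Fraction of each cell SD attributed to the shared
#'   between-fish factor (0-1).
#' @param seed Integer seed (NULL to use the current RNG state).
#' @return Data frame: `fish_id`, `species`, `swim_mode`, `method`,
#'   `value`.
#' @export
simulate_summary_cohort <- function(cells, fish_share = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- NULL
  for (sp in unique(cells$species)) {
    cs <- cells[cells$species == sp, , drop = FALSE]
    nf <- cs$n[1]
    z_fish <- stats::rnorm(nf)
    for (i in seq_len(nf)) {
      id <- sprintf("%s_%02d", gsub(" ", "_", sp), i)
      for (j in seq_len(nrow(cs))) {
        sd_cell <- cs$sem[j] * sqrt(cs$n[j])
        val <- cs$mean[j] + sqrt(fish_share) * sd_cell * z_fish[i] +
          sqrt(1 - fish_share) * sd_cell * stats::rnorm(1)
        out <- rbind(out, data.frame(
          fish_id = id, species = sp, swim_mode = cs$swim_mode[j],
          method = cs$method[j], value = max(val, cs$mean[j] * 0.05),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Simulate a summary-level method-comparison study
#'
#' Draws fish-by-method metabolic summaries directly from a multiplicative
#' generative model: `value = species_mean * fish_factor * method_ratio *
#' exp(noise)`, i.e. a log-scale linear mixed model with a fish random
#' intercept. Used to study the statistical stage (contrast coverage,
#' interaction-removal behaviour) without trace-level simulation.
#'
#' @param species_means Named numeric vector of species mean levels.
#' @param method_ratios Named numeric vector of method level ratios
#'   (default swim : chase : circle = 1 : 1/1.2 : 1/1.25).
#' @param n_per_species Fish per species.
#' @param fish_cv Between-fish CV (shared multiplicative factor).
#' @param resid_cv Residual (within fish x method) CV.
#' @param swim_modes Optional named character vector mapping species to
#'   modes.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @return A data frame: `fish_id`, `species`, `swim_mode`, `method`,
#'   `value`, plus the true log-ratio matrix as attribute `log_ratios`.
#' @export
simulate_method_study <- function(species_means = c(A = 1400, B = 1200,
                                                    C = 1100, D = 1600),
                                  method_ratios = c(swim = 1, chase = 1 / 1.2,
                                                    circle = 1 / 1.25),
                                  n_per_species = 20, fish_cv = 0.20,
                                  resid_cv = 0.10, swim_modes = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- NULL
  sd_resid <- sqrt(log(1 + resid_cv^2))
  for (sp in names(species_means)) {
    f <- lognorm_factor(n_per_species, fish_cv)
    for (i in seq_len(n_per_species)) {
      id <- sprintf("%s%03d", sp, i)
      vals <- species_means[[sp]] * f[i] * method_ratios *
        exp(stats::rnorm(length(method_ratios), -sd_resid^2 / 2, sd_resid))
      out <- rbind(out, data.frame(
        fish_id = id, species = sp,
        swim_mode = if (is.null(swim_modes)) NA_character_ else swim_modes[[sp]],
        method = names(method_ratios), value = unname(vals),
        stringsAsFactors = FALSE))
    }
  }
  lr <- outer(log(method_ratios), log(method_ratios), `-`)
  attr(out, "log_ratios") <- lr
  out
}
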