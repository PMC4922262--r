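#' MMR from an incremental swim trial
#'
#' Maximal metabolic rate is estimated from the MO2 at the maximal swimming
#' speed at which the fish completed at least one full measure/flush cycle:
#' among that speed's completed-cycle windows, the maximum window MO2 is
#' taken (the mean is available via `statistic = "mean"`).
#'
#' @param series An `mo2_series` from [process_trace()].
#' @param speed_map Data frame mapping measurement windows to speeds:
#'   columns `window_start`, `speed_bl_s`, `cycle_complete` (logical), as
#'   produced by [simulate_swim_trial()].
#' @param statistic `"max"` (default) or `"mean"` across the top completed
#'   speed's windows.
#' @return One-row data frame: `mmr`, `speed_bl_s`, `window_start`, `flags`.
#' @export
mmr_swim <- function(series, speed_map, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  m <- merge(as.data.frame(series), speed_map, by = "window_start")
  m <- m[m$cycle_complete, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no speed with a completed full cycle; review the trial protocol")
  top <- max(m$speed_bl_s)
  cand <- m[m$speed_bl_s == top, , drop = FALSE]
  val <- if (statistic == "max") max(cand$mo2) else mean(cand$mo2)
  ws <- cand$window_start[which.max(cand$mo2)]
  data.frame(mmr = val, speed_bl_s = top, window_start = ws,
             flags = paste(unique(cand$flags[cand$flags != ""]),
                           collapse = ";"),
             stringsAsFactors = FALSE)
}

#' MMR from a post-exercise trace (chase or circular chamber)
#'
#' Delegates to [steepest_window_mo2()] with the protocol-appropriate search
#' span: the first 5 min of measurement for the chase protocol, the first
#' 5-7 min (configurable, default 5) for the circular chamber. The trace
#' must begin at measurement onset.
#'
#' @param trace An [oxygen_trace()].
#' @param protocol `"chase"` or `"circle"`.
#' @inheritParams compute_mo2
#' @param span Search span `c(start_s, end_s)`; defaults to `c(0, 300)`
#'   (chase fixed; circle configurable up to `c(0, 420)`).
#' @param window_len_s,stride_s Passed to [steepest_window_mo2()].
#' @return One-row data frame: `mmr`, `window_start`, `window_end`, `r2`,
#'   `flags`.
#' @export
mmr_postexercise <- function(trace, protocol = c("chase", "circle"), fish,
                             chamber, background = NULL, span = NULL,
                             window_len_s = 60, stride_s = 2) {
  protocol <- match.arg(protocol)
  if (is.null(span)) span <- c(0, 300)
  if (protocol == "chase" && !isTRUE(all.equal(span, c(0, 300))))
    stop("chase protocol uses a fixed [0, 300] s search span")
  if (protocol == "circle" && (span[2] > 420 || span[2] < 300))
    stop("circle search span must end within [300, 420] s")
  res <- steepest_window_mo2(trace, span, window_len_s, stride_s, fish,
                             chamber, background)
  e <- res$entry
  data.frame(mmr = e$mo2, window_start = e$window_start,
             window_end = e$window_end, r2 = e$r2, flags = e$flags,
             stringsAsFactors = FALSE)
}

#' SMR as the mean of the lowest fraction of MO2 values
#'
#' Standard metabolic rate is estimated as the average of the lowest 10%
#' (by default) of window MO2 values recorded after the fish has recovered
#' from handling and exercise. `k = ceiling(fraction * n)` values are
#' averaged (at least 1); at least 10 eligible windows are required so a
#' "lowest 10%" cannot degenerate to a single noisy window on short traces.
#'
#' @param series An `mo2_series`.
#' @param recovery_cutoff_s Windows starting before this time are excluded
#'   (default 6 h, the lower bound of the usual 6-12 h recovery wait).
#' @param fraction Fraction of eligible values averaged (default 0.10).
#' @param smr_source Label recorded for provenance.
#' @return One-row data frame: `smr`, `k`, `n_eligible`, `smr_source`.
#' @export
smr_lowest_fraction <- function(series, recovery_cutoff_s = 21600,
                                fraction = 0.10,
                                smr_source = "rest_lowest10") {
  v <- series$mo2[series$window_start >= recovery_cutoff_s]
  if (length(v) < 10)
    stop(sprintf("only %d windows after the %g s recovery cutoff (>= 10 required); use a longer trace",
                 length(v), recovery_cutoff_s))
  k <- max(1L, ceiling(fraction * length(v)))
  data.frame(smr = mean(sort(v)[seq_len(k)]), k = k, n_eligible = length(v),
             smr_source = smr_source, stringsAsFactors = FALSE)
}

#' SMR by extrapolating the MO2-speed relationship to zero speed
#'
#' Fits `MO2(U) = a + b * U^c` (c >= 1) by nonlinear least squares to the
#' swim-trial MO2-speed data; the intercept `a` estimates SMR at zero
#' swimming speed. An exponential form `a * exp(b * U)` is available, for
#' which SMR is also the zero-speed value `a`.
#'
#' @param series An `mo2_series` from a swim trial.
#' @param speed_map As in [mmr_swim()].
#' @param form `"power"` (default) or `"exponential"`.
#' @return One-row data frame: `smr`, `b`, `c` (power form), `rss`,
#'   `smr_source = "extrapolated"`.
#' @export
smr_extrapolate <- function(series, speed_map, form = c("power",
                                                        "exponential")) {
  form <- match.arg(form)
  m <- merge(as.data.frame(series), speed_map, by = "window_start")
  if (length(unique(m$speed_bl_s)) < 3)
    stop("smr_extrapolate needs >= 3 distinct speeds")
  U <- m$speed_bl_s; y <- m$mo2
  fit <- tryCatch(
    if (form == "power") {
      minpack.lm::nlsLM(y ~ a + b * U^c,
                        start = list(a = max(min(y) * 0.8, 1),
                                     b = (max(y) - min(y)) / max(U)^2, c = 2),
                        lower = c(a = 0, b = 1e-12, c = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ a * exp(b * U),
                        start = list(a = max(min(y) * 0.8, 1),
                                     b = log(max(y) / max(min(y), 1)) / max(U)),
                        lower = c(a = 0, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) stop("smr_extrapolate failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  data.frame(smr = unname(cf["a"]), b = unname(cf["b"]),
             c = if (form == "power") unname(cf["c"]) else NA_real_,
             rss = sum(stats::resid(fit)^2), smr_source = "extrapolated",
             stringsAsFactors = FALSE)
}

#' Critical swimming speed (Brett interpolation)
#'
#' `Ucrit = U + U_i * (t / t_i)`: the last fully completed speed plus the
#' increment size pro-rated by the fraction of the failed increment that was
#' swum.
#'
#' @param U Speed at the last fully completed increment (any speed unit).
#' @param U_i Increment size (same unit).
#' @param t Time swum into the failed increment (s), in `[0, t_i]`.
#' @param t_i Time per increment (s), default 1440 (24 min).
#' @return Ucrit in the unit of `U`.
#' @export
ucrit <- function(U, U_i, t, t_i = 1440) {
  stopifnot(U >= 0, U_i > 0, t_i > 0)
  if (t < 0) stop("t must be non-negative")
  if (t > t_i)
    stop("t exceeds t_i: the failed increment appears to have been completed; check increment labelling")
  U + U_i * (t / t_i)
}

#' Solid-blocking correction for swim-tunnel speeds
#'
#' A fish occupying part of the working-section cross-section accelerates
#' the flow around itself; the nominal speed is corrected upward by the
#' fractional error `epsilon = tau0 * lambda * (A_fish / A_tunnel)^(3/2)`.
#' A correction above 5% indicates the fish is too large for the tunnel and
#' raises a warning (5% exactly is accepted).
#'
#' @param speed Nominal speed (any unit); the correction is multiplicative.
#' @param fish_area_m2 Maximal cross-sectional area of the fish (m^2).
#' @param tunnel_area_m2 Working-section cross-sectional area (m^2).
#' @param shape_factor_lambda Dimensionless body-shape factor (default 1).
#' @param dial_tau0 Dimensionless tunnel factor (default 0.8, the classic
#'   fuselage value).
#' @return Corrected speed, with attributes `epsilon` and `warn`
#'   (logical, `epsilon > 0.05`).
#' @export
blocking_correction <- function(speed, fish_area_m2, tunnel_area_m2,
                                shape_factor_lambda = 1, dial_tau0 = 0.8) {
  if (!(fish_area_m2 >= 0) || !(tunnel_area_m2 > 0))
    stop("areas must be positive (fish area may be zero)")
  if (fish_area_m2 >= tunnel_area_m2)
    stop("fish area must be smaller than the tunnel cross-section")
  eps <- dial_tau0 * shape_factor_lambda *
    (fish_area_m2 / tunnel_area_m2)^1.5
  warn <- eps > 0.05
  if (warn)
    warning(sprintf("blocking correction epsilon = %.3f exceeds 5%%", eps))
  structure(speed * (1 + eps), epsilon = eps, warn = warn)
}

#' Aerobic scope
#'
#' The difference between maximal and standard metabolic rate: the capacity
#' for aerobic activity beyond maintenance. A negative scope (SMR estimate
#' above MMR estimate) is returned as-is but flagged with a warning, never
#' silently emitted.
#'
#' @param mmr,smr Rates in mg O2 kg^-1 h^-1.
#' @return `mmr - smr`, with attribute `flagged_negative`.
#' @export
aerobic_scope <- function(mmr, smr) {
  scope <- mmr - smr
  neg <- is.finite(scope) && scope < 0
  if (neg) warning("negative aerobic scope (SMR > MMR); estimates flagged")
  structure(scope, flagged_negative = neg)
}
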