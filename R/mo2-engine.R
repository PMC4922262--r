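#' Background (microbial) respiration model
#'
#' Background O2 uptake is measured as O2 depletion in the empty chamber
#' before and after each trial and assumed to change linearly in time
#' between the two; the rate interpolated to a window's midpoint is
#' subtracted from that window's whole-animal uptake.
#'
#' @param rate_pre,rate_post Whole-chamber uptake rates (mg O2 h^-1), >= 0.
#' @param t_pre,t_post Trial-relative times (s) of the two measurements.
#' @return An object of class `background_model`.
#' @export
background_model <- function(rate_pre = 0, rate_post = 0, t_pre = 0,
                             t_post = 1) {
  stopifnot(rate_pre >= 0, rate_post >= 0, t_post > t_pre)
  structure(list(rate_pre = rate_pre, rate_post = rate_post,
                 t_pre = t_pre, t_post = t_post),
            class = "background_model")
}

#' Interpolate the background rate to a time point
#'
#' Linear in time through (`t_pre`, `rate_pre`) and (`t_post`, `rate_post`);
#' extrapolation outside the interval is linear, floored at zero.
#'
#' @param background A [background_model()] (or NULL for zero background).
#' @param t Time (s).
#' @return Rate in mg O2 h^-1.
#' @export
interpolate_background <- function(background, t) {
  if (is.null(background)) return(0)
  w <- (t - background$t_pre) / (background$t_post - background$t_pre)
  max(0, background$rate_pre + w * (background$rate_post - background$rate_pre))
}

#' Segment a labelled trace into measurement windows
#'
#' Uses per-sample phase labels when present, otherwise derives them from
#' `schedule`. Windows are half-open `[start, end)` in trace time. A partial
#' trailing window is kept only if it spans at least `min_window_s`.
#'
#' @param trace An [oxygen_trace()].
#' @param schedule A [cycle_schedule()], required when the trace carries no
#'   phase labels.
#' @param trim_lead_s Seconds discarded at the start of every window (lets
#'   chamber mixing stabilize after the flush pump stops).
#' @param min_window_s Minimum retained window span (s).
#' @return Data frame with `start_s`, `end_s`, `n` (sample count); zero rows
#'   (with a warning) when no measurement phase exists.
#' @export
segment_windows <- function(trace, schedule = NULL, trim_lead_s = 0,
                            min_window_s = 60) {
  stopifnot(trim_lead_s >= 0)
  tt <- trace$data$time_s
  phase <- trace$data$phase
  if (all(is.na(phase))) {
    if (is.null(schedule))
      stop("trace carries no phase labels and no schedule was supplied")
    phase <- derive_phases(tt, schedule)
  }
  meas <- phase == "measure"
  if (!any(meas, na.rm = TRUE)) {
    warning("no measurement phase found in trace")
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n = integer(0)))
  }
  meas[is.na(meas)] <- FALSE
  r <- rle(meas)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dt <- stats::median(diff(tt))
  out <- do.call(rbind, lapply(keep, function(k) {
    w0 <- tt[starts[k]] + trim_lead_s
    w1 <- tt[ends[k]] + dt        # half-open: window covers its last sample
    n <- sum(tt >= w0 & tt < w1)
    data.frame(start_s = w0, end_s = w1, n = n)
  }))
  out <- out[out$end_s - out$start_s >= min_window_s & out$n >= 3, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the O2-decline slope within a window
#'
#' Ordinary least squares of O2 concentration on time over the half-open
#' window `[start, end)`. The slope S is reported as the magnitude of
#' decline: positive when O2 falls. r2 is NA for a perfectly flat trace
#' (zero total variance).
#'
#' @param trace An [oxygen_trace()].
#' @param window Numeric `c(start_s, end_s)`.
#' @return One-row data frame of class `slope_estimate`: `start_s`, `end_s`,
#'   `S` (mg O2 L^-1 s^-1), `intercept`, `r2`, `n_points`, `o2_min`,
#'   `sat_frac_min`.
#' @export
fit_slope <- function(trace, window) {
  idx <- trace$data$time_s >= window[1] & trace$data$time_s < window[2]
  tt <- trace$data$time_s[idx]
  o2 <- trace$data$o2[idx]
  n <- length(tt)
  if (n < 3) stop(sprintf("fit_slope: window [%g, %g) has %d samples (< 3)",
                          window[1], window[2], n))
  sxx <- sum((tt - mean(tt))^2)
  if (sxx == 0) stop("fit_slope: zero time variance in window")
  b <- sum((tt - mean(tt)) * (o2 - mean(o2))) / sxx
  a <- mean(o2) - b * mean(tt)
  sst <- sum((o2 - mean(o2))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum((o2 - (a + b * tt))^2) / sst
  out <- data.frame(start_s = window[1], end_s = window[2], S = -b,
                    intercept = a, r2 = r2, n_points = n, o2_min = min(o2),
                    sat_frac_min = min(o2) / trace$sat_conc)
  class(out) <- c("slope_estimate", "data.frame")
  out
}

#' Convert a slope estimate to mass-specific oxygen uptake
#'
#' Applies `MO2 = S * V_resp / M` with `V_resp` the chamber volume minus the
#' fish volume, after subtracting the background uptake rate interpolated to
#' the window midpoint. A background-corrected uptake below zero is floored
#' at zero and flagged.
#'
#' @param slope A [fit_slope()] result.
#' @param fish A [fish_record()].
#' @param chamber A [chamber_spec()].
#' @param background A [background_model()] or NULL.
#' @return One-row data frame: `window_start`, `window_end`, `mo2`
#'   (mg O2 kg^-1 h^-1), `r2`, `background_fraction`, `saturation_min`,
#'   `flags`.
#' @export
compute_mo2 <- function(slope, fish, chamber, background = NULL) {
  v_resp <- chamber$volume_l - fish$body_volume_l
  if (v_resp <= 0)
    stop(sprintf("non-positive effective volume for fish '%s' (volume %g L) in %s chamber (%g L)",
                 fish$fish_id, fish$body_volume_l, chamber$protocol,
                 chamber$volume_l))
  uptake <- slope$S * v_resp                           # mg O2 s^-1
  t_mid <- (slope$start_s + slope$end_s) / 2
  bg <- interpolate_background(background, t_mid) / 3600  # mg O2 s^-1
  corrected <- uptake - bg
  flags <- character(0)
  ## flag when the background consumes (numerically) the whole signal
  if (corrected < 0 || (bg > 0 && corrected <= abs(uptake) * 1e-9)) {
    corrected <- 0
    flags <- c(flags, "background_overcorrection")
  }
  data.frame(window_start = slope$start_s, window_end = slope$end_s,
             mo2 = corrected * 3600 / fish$mass_kg, r2 = slope$r2,
             background_fraction = if (uptake > 0) bg / uptake else NA_real_,
             saturation_min = slope$sat_frac_min,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Process a full trace into a per-window MO2 series
#'
#' Segments the trace, fits each window's O2-decline slope and converts it
#' to mass-specific MO2 with background correction. Windows whose minimal
#' O2 falls below 80% air saturation are flagged (never dropped). An
#' optional `min_r2` flags (but keeps) poor fits; no r2 rejection is applied
#' by default.
#'
#' @inheritParams segment_windows
#' @inheritParams compute_mo2
#' @param min_r2 Optional minimal r2; windows below it are flagged
#'   `"low_r2"`.
#' @return Data frame of class `mo2_series` with one row per window and
#'   attributes `fish_id`, `protocol`, `v_resp_l`.
#' @export
process_trace <- function(trace, fish, chamber, schedule = NULL,
                          background = NULL, trim_lead_s = 0,
                          min_window_s = 60, min_r2 = NULL) {
  win <- segment_windows(trace, schedule, trim_lead_s, min_window_s)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sl <- fit_slope(trace, c(win$start_s[i], win$end_s[i]))
    compute_mo2(sl, fish, chamber, background)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_start = numeric(0), window_end = numeric(0),
               mo2 = numeric(0), r2 = numeric(0),
               background_fraction = numeric(0), saturation_min = numeric(0),
               flags = character(0))
  low_sat <- out$saturation_min < 0.8
  out$flags[low_sat] <- paste0(out$flags[low_sat], ";below_80pct_saturation")
  if (!is.null(min_r2)) {
    low <- !is.na(out$r2) & out$r2 < min_r2
    out$flags[low] <- paste0(out$flags[low], ";low_r2")
  }
  out$flags <- sub("^;", "", out$flags)
  attr(out, "fish_id") <- trace$fish_id
  attr(out, "protocol") <- trace$protocol
  attr(out, "v_resp_l") <- chamber$volume_l - fish$body_volume_l
  class(out) <- c("mo2_series", "data.frame")
  out
}

#' Steepest fixed-length window within a search span
#'
#' Slides a `window_len_s` window across `search_span` at `stride_s`
#' (default: the 2 s sampling interval, i.e. exhaustive at sample
#' resolution), fits each window's slope and returns the window of maximal
#' O2-decline magnitude converted to MO2. Ties are broken by the earliest
#' window start. This implements the "steepest 1-min slope" rule used to
#' estimate post-exercise maximal uptake.
#'
#' @param trace An [oxygen_trace()].
#' @param search_span Numeric `c(start_s, end_s)`.
#' @param window_len_s Window length (s), default 60.
#' @param stride_s Scan stride (s), default 2.
#' @inheritParams compute_mo2
#' @return A list: `entry` (as [compute_mo2()]) and `window`
#'   (`c(start, end)`).
#' @export
steepest_window_mo2 <- function(trace, search_span, window_len_s = 60,
                                stride_s = 2, fish, chamber,
                                background = NULL) {
  if (diff(search_span) < window_len_s)
    stop("search span is shorter than the window length")
  starts <- seq(search_span[1], search_span[2] - window_len_s, by = stride_s)
  fits <- lapply(starts, function(s) fit_slope(trace, c(s, s + window_len_s)))
  S <- vapply(fits, `[[`, numeric(1), "S")
  ## earliest window among ties, robust to last-ulp float jitter
  tol <- max(1e-12, abs(max(S)) * 1e-9)
  best <- fits[[which(S >= max(S) - tol)[1]]]
  list(entry = compute_mo2(best, fish, chamber, background),
       window = c(best$start_s, best$end_s))
}
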