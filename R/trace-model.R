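#' @keywords internal
"_PACKAGE"

## Protocols recognised throughout the package. "rest" is the post-chase
## resting chamber; "chase" traces are recorded in the same chamber but start
## at the post-exercise measurement onset.
PROTOCOLS <- c("swim", "chase", "circle", "rest")
PHASES <- c("measure", "flush", "ramp", "habituation")

#' Default dissolved-oxygen concentration at 100% air saturation
#'
#' Concentration of dissolved O2 (mg L^-1) in seawater at 28.5 degC and full
#' air saturation, used as the flush target and the reference for the 80%
#' saturation audit. This is a documented configuration constant, not a
#' solubility model: supply your own value for other temperatures or
#' salinities via the `sat_conc` argument of [oxygen_trace()].
#'
#' @format A length-one numeric (mg O2 L^-1).
#' @export
sat_conc_default <- 6.2

#' Measurement/flush cycle schedule
#'
#' Intermittent-flow respirometry alternates sealed measurement periods with
#' flush periods that restore full air saturation. The default is the common
#' 8-min cycle: 5 min measurement + 3 min flush.
#'
#' @param measure_s Measurement period duration (s), > 0.
#' @param flush_s Flush period duration (s), >= 0.
#' @param start_offset_s Time of the first measurement start (s from trial
#'   start); samples before it are labelled "habituation".
#' @return An object of class `cycle_schedule`.
#' @export
cycle_schedule <- function(measure_s = 300, flush_s = 180, start_offset_s = 0) {
  stopifnot(measure_s > 0, flush_s >= 0, start_offset_s >= 0)
  structure(list(measure_s = measure_s, flush_s = flush_s,
                 start_offset_s = start_offset_s),
            class = "cycle_schedule")
}

cycle_len <- function(schedule) schedule$measure_s + schedule$flush_s

#' Per-fish metadata record
#'
#' @param fish_id Identifier (character scalar).
#' @param species Species name.
#' @param swim_mode Locomotory mode: `"BCF"` (body-caudal fin) or `"MPF"`
#'   (median-paired fin).
#' @param mass_kg Wet mass in kilograms (the M of the MO2 equation).
#' @param standard_length_m Standard length in metres (basis of BL s^-1).
#' @param body_volume_l Fish volume in litres, subtracted from the chamber
#'   volume to give the effective respirometer volume. Defaults to
#'   `mass_kg * 1.0` L kg^-1 (fish are close to neutrally buoyant, density
#'   approximately that of water); override when measured directly.
#' @param cross_section_area_m2 Maximal cross-sectional area (m^2), used by
#'   the solid-blocking correction; optional.
#' @return An object of class `fish_record`.
#' @export
fish_record <- function(fish_id, species, swim_mode = c("BCF", "MPF"),
                        mass_kg, standard_length_m,
                        body_volume_l = mass_kg * 1.0,
                        cross_section_area_m2 = NA_real_) {
  swim_mode <- match.arg(swim_mode)
  stopifnot(mass_kg > 0, standard_length_m > 0, body_volume_l > 0)
  structure(list(fish_id = as.character(fish_id), species = species,
                 swim_mode = swim_mode, mass_kg = mass_kg,
                 standard_length_m = standard_length_m,
                 body_volume_l = body_volume_l,
                 cross_section_area_m2 = cross_section_area_m2),
            class = "fish_record")
}

#' Respirometry chamber specification
#'
#' Default gross volumes follow typical small-reef-fish setups: a 4.8 L
#' swim tunnel, a 1.615 L resting chamber and a 2.654 L circular chamber.
#'
#' @param protocol One of `"swim"`, `"chase"`, `"circle"`, `"rest"`.
#' @param volume_l Gross chamber volume (L). If missing, the protocol
#'   default is used.
#' @param working_section Optional numeric `c(width, length, depth)` in m,
#'   swim tunnels only.
#' @param tunnel_cross_section_area_m2 Working-section cross-sectional area
#'   (m^2); computed from `working_section` when absent.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(protocol = c("swim", "chase", "circle", "rest"),
                         volume_l = NULL, working_section = NULL,
                         tunnel_cross_section_area_m2 = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(volume_l)) {
    volume_l <- switch(protocol, swim = 4.8, chase = 1.615, rest = 1.615,
                       circle = 2.654)
  }
  stopifnot(volume_l > 0)
  if (is.null(tunnel_cross_section_area_m2) && !is.null(working_section)) {
    tunnel_cross_section_area_m2 <- working_section[1] * working_section[3]
  }
  structure(list(protocol = protocol, volume_l = volume_l,
                 working_section = working_section,
                 tunnel_cross_section_area_m2 = tunnel_cross_section_area_m2),
            class = "chamber_spec")
}

#' Incremental swim-trial schedule
#'
#' Standard Ucrit protocol: habituation at a low speed, a ramp to the start
#' speed, then stepped increments with several measure/flush cycles per
#' speed until fatigue.
#'
#' @param habituation_speed_bl_s Habituation speed (BL s^-1).
#' @param start_speed_bl_s First stepped speed (BL s^-1).
#' @param increment_bl_s Speed increment U_i (BL s^-1).
#' @param cycles_per_speed Measure/flush cycles per speed step.
#' @param cycle Cycle schedule; time per speed t_i is
#'   `cycles_per_speed * (measure_s + flush_s)` (default 3 x 480 s = 24 min).
#' @param ramp_s Ramp duration from habituation to start speed (s).
#' @return An object of class `swim_schedule`.
#' @export
swim_schedule <- function(habituation_speed_bl_s = 0.5, start_speed_bl_s = 4.0,
                          increment_bl_s = 0.5, cycles_per_speed = 3,
                          cycle = cycle_schedule(), ramp_s = 240) {
  stopifnot(habituation_speed_bl_s > 0, start_speed_bl_s > 0,
            increment_bl_s > 0, cycles_per_speed >= 1, ramp_s >= 0)
  structure(list(habituation_speed_bl_s = habituation_speed_bl_s,
                 start_speed_bl_s = start_speed_bl_s,
                 increment_bl_s = increment_bl_s,
                 cycles_per_speed = cycles_per_speed,
                 time_per_speed_s = cycles_per_speed * cycle_len(cycle),
                 ramp_s = ramp_s),
            class = "swim_schedule")
}

#' Construct a validated oxygen trace
#'
#' The raw signal every estimator consumes: dissolved O2 concentration
#' sampled (nominally at 0.5 Hz) during a respirometry trial, with optional
#' per-sample phase labels.
#'
#' @param fish_id Identifier.
#' @param protocol One of `"swim"`, `"chase"`, `"circle"`, `"rest"`.
#' @param time_s Sample times, seconds from trial start, strictly increasing.
#' @param o2 Dissolved O2 concentration (mg L^-1), > 0.
#' @param temp_c Optional water temperature (degC).
#' @param phase Optional per-sample labels among `"measure"`, `"flush"`,
#'   `"ramp"`, `"habituation"`; derived from `schedule` when absent.
#' @param sat_conc O2 concentration at 100% air saturation (mg L^-1).
#' @param schedule Optional [cycle_schedule()] used to derive phase labels.
#' @param nominal_dt_s Expected sampling interval (s); larger gaps are
#'   flagged (not dropped).
#' @return An object of class `oxygen_trace`: a list with a `data` frame
#'   (`time_s`, `o2`, `temp_c`, `phase`), `fish_id`, `protocol`, `sat_conc`
#'   and a character vector of `flags`.
#' @export
oxygen_trace <- function(fish_id, protocol, time_s, o2, temp_c = NULL,
                         phase = NULL, sat_conc = sat_conc_default,
                         schedule = NULL, nominal_dt_s = 2) {
  protocol <- match.arg(protocol, PROTOCOLS)
  time_s <- as.numeric(time_s); o2 <- as.numeric(o2)
  if (length(time_s) != length(o2))
    stop("time_s and o2 must have equal length")
  d <- diff(time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1L
    stop(sprintf("time_s must be strictly increasing; first violation at index %d (t = %g)",
                 i, time_s[i]))
  }
  if (any(o2 <= 0))
    stop(sprintf("o2 must be positive; first violation at index %d",
                 which(o2 <= 0)[1]))
  if (!(sat_conc > 0)) stop("sat_conc must be positive")
  flags <- character(0)
  if (any(d > nominal_dt_s * 1.5)) {
    flags <- c(flags, sprintf("sampling_gaps:%d", sum(d > nominal_dt_s * 1.5)))
  }
  if (is.null(phase) && !is.null(schedule)) {
    phase <- derive_phases(time_s, schedule)
  }
  if (!is.null(phase)) {
    phase <- as.character(phase)
    bad <- setdiff(unique(phase), PHASES)
    if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  } else {
    phase <- rep(NA_character_, length(time_s))
  }
  if (is.null(temp_c)) temp_c <- rep(NA_real_, length(time_s))
  structure(list(fish_id = as.character(fish_id), protocol = protocol,
                 data = data.frame(time_s = time_s, o2 = o2,
                                   temp_c = temp_c, phase = phase),
                 sat_conc = sat_conc, flags = flags),
            class = "oxygen_trace")
}

#' Derive measure/flush phase labels from a cycle schedule
#'
#' Windows are half-open `[start, end)`: a sample at exactly the boundary
#' belongs to the next phase. Samples before `start_offset_s` are labelled
#' `"habituation"`.
#'
#' @param time_s Sample times (s).
#' @param schedule A [cycle_schedule()].
#' @return Character vector of phase labels, one per sample.
#' @export
derive_phases <- function(time_s, schedule) {
  rel <- time_s - schedule$start_offset_s
  pos <- rel %% cycle_len(schedule)
  out <- ifelse(pos < schedule$measure_s, "measure", "flush")
  out[rel < 0] <- "habituation"
  out
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf("<oxygen_trace> fish %s, protocol %s: %d samples over %.0f s",
              x$fish_id, x$protocol, nrow(x$data), diff(range(x$data$time_s))))
  if (length(x$flags)) cat(" [flags: ", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read an oxygen trace from CSV
#'
#' One fixed dialect: comma-separated, dot decimal, UTF-8, mandatory header.
#' Required columns `time_s` and `o2_mg_per_l`; optional `temp_c` and
#' `phase`. When `phase` is absent and a `schedule` is given, phase labels
#' are derived from the schedule.
#'
#' @param path CSV file path.
#' @param schedule Optional [cycle_schedule()] for phase derivation.
#' @param fish_id,protocol,sat_conc Trace attributes not stored in the CSV.
#' @return An [oxygen_trace()].
#' @export
read_trace <- function(path, schedule = NULL, fish_id = "unknown",
                       protocol = "rest", sat_conc = sat_conc_default) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("time_s", "o2_mg_per_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("trace format error in '%s': missing required column(s) %s",
                 path, paste(miss, collapse = ", ")))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 !is.finite(suppressWarnings(as.numeric(df$o2_mg_per_l))))
  if (length(bad))
    stop(sprintf("malformed rows in '%s' (data lines, excluding header): %s",
                 path, paste(utils::head(bad + 1L, 10), collapse = ", ")))
  oxygen_trace(fish_id = fish_id, protocol = protocol,
               time_s = df$time_s, o2 = df$o2_mg_per_l,
               temp_c = if ("temp_c" %in% names(df)) df$temp_c else NULL,
               phase = if ("phase" %in% names(df)) df$phase else NULL,
               sat_conc = sat_conc, schedule = schedule)
}

#' Write an oxygen trace to CSV
#'
#' @param trace An [oxygen_trace()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  df <- trace$data
  names(df)[names(df) == "o2"] <- "o2_mg_per_l"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One fish-by-method metabolic summary record
#'
#' The unit of statistical comparison: for one fish under one protocol, the
#' estimated MMR, SMR, aerobic scope and (swim trials) Ucrit.
#'
#' @param fish_id,species,swim_mode Metadata carried through from the fish
#'   record.
#' @param method Protocol that produced the estimates: `"swim"`, `"chase"`
#'   or `"circle"`.
#' @param mmr,smr,aerobic_scope Rates in mg O2 kg^-1 h^-1 (NA when not
#'   estimated).
#' @param smr_source How SMR was obtained: `"rest_lowest10"`,
#'   `"circle_lowest10"` or `"extrapolated"`.
#' @param ucrit_abs_cm_s,ucrit_rel_bl_s Critical swimming speed, absolute
#'   and relative.
#' @param flags Semicolon-separated diagnostic flags.
#' @return A one-row data frame of class `metabolic_summary`.
#' @export
metabolic_summary <- function(fish_id, species = NA_character_,
                              swim_mode = NA_character_,
                              method = c("swim", "chase", "circle"),
                              mmr = NA_real_, smr = NA_real_,
                              smr_source = NA_character_,
                              aerobic_scope = NA_real_,
                              ucrit_abs_cm_s = NA_real_,
                              ucrit_rel_bl_s = NA_real_, flags = "") {
  method <- match.arg(method)
  out <- data.frame(fish_id = as.character(fish_id), species = species,
                    swim_mode = swim_mode, method = method, mmr = mmr,
                    smr = smr, smr_source = smr_source,
                    aerobic_scope = aerobic_scope,
                    ucrit_abs_cm_s = ucrit_abs_cm_s,
                    ucrit_rel_bl_s = ucrit_rel_bl_s, flags = flags,
                    stringsAsFactors = FALSE)
  class(out) <- c("metabolic_summary", "data.frame")
  out
}

summary_metric_cols <- c("mmr", "smr", "aerobic_scope",
                         "ucrit_abs_cm_s", "ucrit_rel_bl_s")
summary_units <- c(mmr = "mg_O2_kg-1_h-1", smr = "mg_O2_kg-1_h-1",
                   aerobic_scope = "mg_O2_kg-1_h-1",
                   ucrit_abs_cm_s = "cm_s-1", ucrit_rel_bl_s = "BL_s-1")

#' Write metabolic summaries to a tidy results CSV
#'
#' One row per fish x method x metric; only metrics that were actually
#' estimated (non-NA) are written. The table round-trips through
#' [read_results()].
#'
#' @param records A `metabolic_summary` data frame (one or more rows, e.g.
#'   `rbind` of [metabolic_summary()] records).
#' @param path Output CSV path.
#' @export
write_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("write_results: 'records' must be non-empty")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    keep <- summary_metric_cols[!is.na(unlist(r[summary_metric_cols]))]
    if (!length(keep)) return(NULL)
    data.frame(fish_id = r$fish_id, species = r$species,
               swim_mode = r$swim_mode, method = r$method, metric = keep,
               value = as.numeric(unlist(r[keep])),
               unit = unname(summary_units[keep]),
               smr_source = ifelse(keep == "smr", r$smr_source, NA_character_),
               flags = r$flags, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  ok <- tryCatch(
    utils::write.csv(format_num_df(long, "value"), path, row.names = FALSE,
                     quote = FALSE, na = ""),
    error = function(e) stop(sprintf("write_results: cannot write '%s': %s",
                                     path, conditionMessage(e))))
  invisible(path)
}

## full-precision numeric formatting so write/read round-trips to < 1e-12
format_num_df <- function(df, cols) {
  for (cl in cols) df[[cl]] <- formatC(df[[cl]], digits = 17, format = "g")
  df
}

#' Read a tidy results CSV back into a metabolic-summary table
#'
#' @param path CSV written by [write_results()].
#' @return A `metabolic_summary` data frame (wide, one row per fish x method).
#' @export
read_results <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("fish_id", "method", "metric", "value")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop(sprintf("results format error in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  key <- interaction(long$fish_id, long$method, drop = TRUE)
  rows <- lapply(split(long, key), function(g) {
    out <- metabolic_summary(fish_id = g$fish_id[1], species = g$species[1],
                             swim_mode = g$swim_mode[1], method = g$method[1],
                             flags = if ("flags" %in% names(g) && !is.na(g$flags[1])) g$flags[1] else "")
    for (i in seq_len(nrow(g))) {
      out[[g$metric[i]]] <- g$value[i]
      if (g$metric[i] == "smr" && "smr_source" %in% names(g))
        out$smr_source <- g$smr_source[i]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metabolic_summary", "data.frame")
  out
}
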