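#' Derive Ucrit inputs from a swim-trial speed map and trace
#'
#' The failed increment starts one full cycle after the last completed
#' window at the top completed speed; the time swum into it is read off the
#' trace end.
#'
#' @param speed_map As produced by [simulate_swim_trial()].
#' @param trace The swim-trial [oxygen_trace()].
#' @param t_i Time per increment (s).
#' @param cycle_len_s Full cycle length (s).
#' @param dt_s Sampling interval (s).
#' @return A list: `U` (last completed speed, BL s^-1), `U_i`, `t`, `t_i`.
#' @export
ucrit_inputs_from_trial <- function(speed_map, trace, t_i = 1440,
                                    cycle_len_s = 480, dt_s = 2) {
  comp <- speed_map[speed_map$cycle_complete, , drop = FALSE]
  if (nrow(comp) == 0) stop("no completed cycle in speed map")
  ## a speed counts as a completed increment only when all of its cycles
  ## (t_i / cycle length) were finished; the top such speed is Brett's U
  per_speed <- tapply(comp$cycle_complete, comp$speed_bl_s, sum)
  full <- as.numeric(names(per_speed))[per_speed >= round(t_i / cycle_len_s)]
  if (!length(full)) stop("no fully completed increment in speed map")
  U <- max(full)
  us <- sort(unique(speed_map$speed_bl_s))
  U_i <- if (length(us) > 1) stats::median(diff(us)) else
    stop("cannot infer the speed increment from a single speed")
  failed_start <- max(comp$window_start[comp$speed_bl_s == U]) + cycle_len_s
  t_end <- max(trace$data$time_s) + dt_s
  t <- min(max(t_end - failed_start, 0), t_i)
  list(U = U, U_i = U_i, t = t, t_i = t_i)
}

#' Estimate per-fish metabolic summaries from a simulated or measured cohort
#'
#' The metrics stage: for every fish x protocol trace, computes the MO2
#' series and the protocol-appropriate MMR, SMR, aerobic scope and (swim)
#' Ucrit estimates.
#'
#' @param cohort A list as returned by [simulate_cohort()] (`traces`,
#'   `fish`, `backgrounds`, `speed_maps`).
#' @param chambers Named list of [chamber_spec()] per protocol.
#' @param cycles A [cycle_schedule()].
#' @param smr_fraction,recovery_cutoff_s Passed to [smr_lowest_fraction()].
#' @param circle_span_end End of the circle steepest-window search span (s).
#' @param stride_s,trim_lead_s Engine options.
#' @param t_i Swim-trial time per increment (s).
#' @return A `metabolic_summary` data frame, one row per fish x method.
#' @export
estimate_summaries <- function(cohort,
                               chambers = list(swim = chamber_spec("swim"),
                                               chase = chamber_spec("chase"),
                                               circle = chamber_spec("circle")),
                               cycles = cycle_schedule(),
                               smr_fraction = 0.10,
                               recovery_cutoff_s = 21600,
                               circle_span_end = 300, stride_s = 2,
                               trim_lead_s = 0, t_i = 1440) {
  out <- NULL
  for (key in names(cohort$traces)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    id <- parts[1]; proto <- parts[2]
    trace <- cohort$traces[[key]]
    fish <- cohort$fish[[id]]
    bg <- cohort$backgrounds[[key]]
    chamber <- chambers[[proto]]
    rec <- tryCatch({
      if (proto == "swim") {
        series <- process_trace(trace, fish, chamber, background = bg,
                                trim_lead_s = trim_lead_s)
        mm <- mmr_swim(series, cohort$speed_maps[[key]])
        ui <- ucrit_inputs_from_trial(cohort$speed_maps[[key]], trace,
                                      t_i = t_i,
                                      cycle_len_s = cycle_len(cycles))
        ucr <- ucrit(ui$U, ui$U_i, ui$t, ui$t_i)
        metabolic_summary(id, fish$species, fish$swim_mode, method = "swim",
                          mmr = mm$mmr,
                          ucrit_rel_bl_s = ucr,
                          ucrit_abs_cm_s = ucr * fish$standard_length_m * 100,
                          flags = mm$flags)
      } else {
        series <- process_trace(trace, fish, chamber, background = bg,
                                trim_lead_s = trim_lead_s)
        span <- if (proto == "circle") c(0, circle_span_end) else c(0, 300)
        mm <- mmr_postexercise(trace, proto, fish, chamber, background = bg,
                               span = span, stride_s = stride_s)
        sm <- smr_lowest_fraction(series, recovery_cutoff_s, smr_fraction,
                                  smr_source = if (proto == "circle")
                                    "circle_lowest10" else "rest_lowest10")
        metabolic_summary(id, fish$species, fish$swim_mode, method = proto,
                          mmr = mm$mmr, smr = sm$smr,
                          smr_source = sm$smr_source,
                          aerobic_scope = as.numeric(aerobic_scope(mm$mmr,
                                                                   sm$smr)),
                          flags = mm$flags)
      }
    }, error = function(e) {
      stop(sprintf("metrics stage failed for fish %s (%s): %s", id, proto,
                   conditionMessage(e)), call. = FALSE)
    })
    out <- rbind(out, rec)
  }
  rownames(out) <- NULL
  class(out) <- c("metabolic_summary", "data.frame")
  out
}

#' Build a run configuration
#'
#' A fully serializable description of one pipeline run: cohort design,
#' chamber volumes, cycle schedule, sensor model, estimator options and
#' comparison options. Every run writes its resolved configuration next to
#' its outputs.
#'
#' @param seed Integer seed governing every random draw in the run.
#' @param design Cohort design table; see [default_cohort_design()].
#' @param chambers Named list of gross chamber volumes (L).
#' @param cycles List: `measure_s`, `flush_s`.
#' @param sensor List of [sensor_model()] fields.
#' @param durations List: `resting_duration_s`, `habituation_s`.
#' @param activity_cv Spontaneous-activity CV per window.
#' @param estimators List: `smr_fraction`, `recovery_cutoff_s`,
#'   `circle_span_end`, `stride_s`, `trim_lead_s`.
#' @param comparison List: `alpha`, `adjust`, `transform`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, design = default_cohort_design(),
                       chambers = list(swim = 4.8, chase = 1.615,
                                       circle = 2.654),
                       cycles = list(measure_s = 300, flush_s = 180),
                       sensor = list(noise_sd = 0.01,
                                     background_rate_0 = 0.05,
                                     background_slope = 0.005,
                                     flush_mode = "instant"),
                       durations = list(resting_duration_s = 28800,
                                        habituation_s = 1920),
                       activity_cv = 0.03,
                       estimators = list(smr_fraction = 0.10,
                                         recovery_cutoff_s = 21600,
                                         circle_span_end = 300,
                                         stride_s = 2, trim_lead_s = 0),
                       comparison = list(alpha = 0.05, adjust = "mvt",
                                         transform = "identity")) {
  cfg <- list(seed = seed, design = design, chambers = chambers,
              cycles = cycles, sensor = sensor, durations = durations,
              activity_cv = activity_cv, estimators = estimators,
              comparison = comparison)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Fails before any computation when a required field is missing or
#' non-positive.
#'
#' @param config A `run_config` (or plain list).
#' @return The config, invisibly, when valid.
#' @export
validate_run_config <- function(config) {
  for (p in c("swim", "chase", "circle")) {
    v <- config$chambers[[p]]
    if (is.null(v) || !is.numeric(v) || !(v > 0))
      stop(sprintf("config validation: chamber volume for '%s' missing or non-positive", p))
  }
  if (is.null(config$seed)) stop("config validation: seed missing")
  if (is.null(config$cycles$measure_s) || !(config$cycles$measure_s > 0))
    stop("config validation: cycles$measure_s missing or non-positive")
  if (is.null(config$design) || !nrow(as.data.frame(config$design)))
    stop("config validation: empty cohort design")
  invisible(config)
}

#' Read a run configuration from a YAML file
#'
#' Values in the file override the defaults of [run_config()]; the `design`
#' section, when present, must be a table-like mapping of per-species
#' parameters.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) raw$design <- as.data.frame(raw$design)
  base <- run_config()
  for (nm in names(raw)) {
    if (is.list(base[[nm]]) && is.list(raw[[nm]]) && nm != "design") {
      for (k in names(raw[[nm]])) base[[nm]][[k]] <- raw[[nm]][[k]]
    } else base[[nm]] <- raw[[nm]]
  }
  validate_run_config(base)
  base
}

#' Run the full pipeline: simulate, process, estimate, compare
#'
#' Chains the four stages under one seed, writing every artifact (trace
#' CSVs, metadata, ground truth, MO2 series, metabolic summaries,
#' comparison report, resolved configuration) plus a checksum manifest to
#' `out_dir`. Identical configurations produce identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cycles <- cycle_schedule(config$cycles$measure_s, config$cycles$flush_s)
  sensor <- do.call(sensor_model, config$sensor)
  chambers <- list(
    swim = chamber_spec("swim", config$chambers$swim),
    chase = chamber_spec("chase", config$chambers$chase),
    circle = chamber_spec("circle", config$chambers$circle))

  say("stage simulate: seed %d, %d species", config$seed,
      nrow(config$design))
  cohort <- simulate_cohort(config$design, sensor, cycles,
                            seed = config$seed,
                            resting_duration_s = config$durations$resting_duration_s,
                            habituation_s = config$durations$habituation_s,
                            activity_cv = config$activity_cv,
                            chambers = chambers)
  files <- character(0)
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  for (key in names(cohort$traces)) {
    f <- file.path(trace_dir, paste0(key, ".csv"))
    write_trace(cohort$traces[[key]], f)
    files <- c(files, f)
  }
  f_meta <- file.path(out_dir, "metadata.csv")
  utils::write.csv(cohort$metadata, f_meta, row.names = FALSE)
  f_gt <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(cohort$ground_truth, f_gt, row.names = FALSE)
  files <- c(files, f_meta, f_gt)

  say("stage process: %d traces", length(cohort$traces))
  est <- config$estimators
  mo2_all <- NULL
  for (key in names(cohort$traces)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    series <- tryCatch(
      process_trace(cohort$traces[[key]], cohort$fish[[parts[1]]],
                    chambers[[parts[2]]],
                    background = cohort$backgrounds[[key]],
                    trim_lead_s = est$trim_lead_s),
      error = function(e) stop(sprintf("process stage failed for fish %s (%s): %s",
                                       parts[1], parts[2],
                                       conditionMessage(e)), call. = FALSE))
    if (nrow(series)) {
      series$fish_id <- parts[1]; series$protocol <- parts[2]
      mo2_all <- rbind(mo2_all, as.data.frame(series))
    }
  }
  f_mo2 <- file.path(out_dir, "mo2_series.csv")
  utils::write.csv(format_num_df(mo2_all, "mo2"), f_mo2, row.names = FALSE)
  files <- c(files, f_mo2)

  say("stage metrics")
  summaries <- estimate_summaries(cohort, chambers, cycles,
                                  smr_fraction = est$smr_fraction,
                                  recovery_cutoff_s = est$recovery_cutoff_s,
                                  circle_span_end = est$circle_span_end,
                                  stride_s = est$stride_s,
                                  trim_lead_s = est$trim_lead_s)
  f_sum <- file.path(out_dir, "summaries.csv")
  write_results(summaries, f_sum)
  files <- c(files, f_sum)

  say("stage compare")
  cmp <- config$comparison
  report <- list(seed = config$seed)
  for (resp in c("mmr", "smr")) {
    res <- tryCatch(
      fit_comparison(summaries, resp, transform = cmp$transform,
                     alpha = cmp$alpha, adjust = cmp$adjust),
      error = function(e) NULL)
    if (!is.null(res))
      report[[resp]] <- list(fixed_effect_tests = res$fixed_effect_tests,
                             interaction_dropped = res$interaction$dropped,
                             contrasts = res$contrasts,
                             predictions = res$predictions,
                             percent_differences = res$percent_differences)
  }
  uc <- summaries[summaries$method == "swim" &
                    !is.na(summaries$ucrit_abs_cm_s), , drop = FALSE]
  if (nrow(uc) && length(unique(uc$species)) > 1) {
    for (resp in c("ucrit_abs_cm_s", "ucrit_rel_bl_s")) {
      res <- tryCatch(fit_ucrit_lm(uc, resp, alpha = cmp$alpha),
                      error = function(e) NULL)
      if (!is.null(res))
        report[[resp]] <- list(fixed_effect_tests = res$fixed_effect_tests,
                               species_means = as.list(res$species_means),
                               letters = as.list(res$letters),
                               mode_means = as.list(res$mode_means))
    }
  }
  f_rep <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(report, f_rep, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  files <- c(files, f_rep)

  f_cfg <- file.path(out_dir, "run_config.yaml")
  cfg_out <- unclass(config)
  cfg_out$design <- as.list(as.data.frame(config$design))
  yaml::write_yaml(cfg_out, f_cfg)
  files <- c(files, f_cfg)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  say("pipeline complete: %d files in %s", nrow(manifest) + 1L, out_dir)
  invisible(manifest)
}
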