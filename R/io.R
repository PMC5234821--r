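
# Full-precision decimal rendering so read(write(x)) is numerically exact.
fmt_num <- function(x) sprintf("%.17g", x)

trial_file_stem <- function(r) {
  sprintf("trial_s%02d_t%02d_%s", as.integer(r$subject_id),
          as.integer(r$trial_id), r$condition)
}

#' Write an experiment as delimited trial logs
#'
#' One CSV per trial (`subject_id, trial_id, condition, t_s, x_lead_m,
#' v_lead_ms, x_fol_m, v_fol_ms`), a companion glance-onset CSV per occluded
#' trial (`subject_id, trial_id, glance_onset_s`), and a JSON manifest with
#' seeds, parameters, crash flags, dt and trial length. Numbers are written
#' with 17 significant digits so the round trip through text is exact.
#'
#' @param records List of `trial_record`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_trials = length(records), trials = list())
  for (r in records) {
    stem <- trial_file_stem(r)
    df <- data.frame(subject_id = r$subject_id, trial_id = r$trial_id,
                     condition = r$condition, t_s = fmt_num(r$t),
                     x_lead_m = fmt_num(r$x_lead),
                     v_lead_ms = fmt_num(r$v_lead),
                     x_fol_m = fmt_num(r$x_fol),
                     v_fol_ms = fmt_num(r$v_fol))
    utils::write.csv(df, file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (r$condition == "occluded") {
      gdf <- data.frame(subject_id = rep(r$subject_id,
                                         length(r$glance_onsets)),
                        trial_id = rep(r$trial_id, length(r$glance_onsets)),
                        glance_onset_s = fmt_num(r$glance_onsets))
      utils::write.csv(gdf, file.path(dir, paste0(stem, "_glances.csv")),
                       row.names = FALSE, quote = FALSE)
    }
    manifest$trials[[stem]] <- list(
      subject_id = r$subject_id, trial_id = r$trial_id,
      condition = r$condition, seed = r$seed, dt = r$dt,
      trial_length = r$trial_length, crashed = r$crashed,
      params = unclass(r$params))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment written by [write_trials()]
#'
#' @param dir Directory containing the trial logs and `manifest.json`.
#' @return List of `trial_record`s.
#' @export
read_trials <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  records <- lapply(names(manifest$trials), function(stem) {
    meta <- manifest$trials[[stem]]
    f <- file.path(dir, paste0(stem, ".csv"))
    if (!file.exists(f)) stop("trial log missing: ", f)
    df <- utils::read.csv(f, colClasses = c(
      subject_id = "integer", trial_id = "integer", condition = "character",
      t_s = "numeric", x_lead_m = "numeric", v_lead_ms = "numeric",
      x_fol_m = "numeric", v_fol_ms = "numeric"))
    required <- c("subject_id", "trial_id", "condition", "t_s", "x_lead_m",
                  "v_lead_ms", "x_fol_m", "v_fol_ms")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0L) {
      stop(sprintf("file %s is missing column(s): %s", f,
                   paste(missing_cols, collapse = ", ")))
    }
    onsets <- numeric(0)
    if (meta$condition == "occluded") {
      gf <- file.path(dir, paste0(stem, "_glances.csv"))
      if (!file.exists(gf)) {
        stop("glance file missing for occluded trial: ", stem)
      }
      gdf <- utils::read.csv(gf)
      onsets <- as.numeric(gdf$glance_onset_s)
    }
    p <- meta$params
    params <- driver_params(T0 = p$T0, c = p$c, beta = p$beta,
                            o_base = p$o_base, o_min = p$o_min,
                            o_max = p$o_max, glance_dur = p$glance_dur,
                            k_speed = p$k_speed, k_gap = p$k_gap,
                            gap_accel_cap = p$gap_accel_cap,
                            accel_bounds = unlist(p$accel_bounds),
                            noise_sd = p$noise_sd,
                            glance_noise_sd = p$glance_noise_sd %||% 0,
                            variant = p$variant,
                            hoogendoorn_TH = p$hoogendoorn_TH,
                            hoogendoorn_md_scale = p$hoogendoorn_md_scale,
                            vehicle_length = p$vehicle_length)
    sched_o <- if (length(onsets) >= 2L) {
      diff(onsets) - params$glance_dur
    } else numeric(0)
    structure(list(subject_id = df$subject_id[1], trial_id = df$trial_id[1],
                   condition = meta$condition,
                   seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                   dt = meta$dt, trial_length = meta$trial_length,
                   t = df$t_s, x_lead = df$x_lead_m, v_lead = df$v_lead_ms,
                   x_fol = df$x_fol_m, v_fol = df$v_fol_ms,
                   glance_onsets = onsets, sched_o = sched_o,
                   crashed = isTRUE(meta$crashed),
                   o_state = NULL, params = params),
              class = "trial_record")
  })
  records
}

#' Run the full analysis pipeline on an experiment
#'
#' Preprocess (trim/filter, per-subject aggregates), between-subjects
#' analysis (correlation comparison, headway slope, capability estimates)
#' and within-trial glance analysis, collected into one report.
#'
#' @param records List of `trial_record`s.
#' @param include_crashed Keep crashed trials (default FALSE).
#' @param pool Per-subject pooling, `"samples"` or `"trials"`.
#' @return List of class `analysis_report` with components `summaries`,
#'   `comparison`, `slope`, `capability` (per-subject data.frame), `glance`,
#'   `exclusions`.
#' @export
analyze_experiment <- function(records, include_crashed = FALSE,
                               pool = "samples") {
  summaries <- summarize_subjects(records, include_crashed = include_crashed,
                                  pool = pool)
  if (is.null(summaries) || nrow(summaries) < 4L) {
    stop("fewer than 4 usable subjects")
  }
  comparison <- compare_models(summaries)
  slope <- fit_headway_slope(summaries)
  capability <- data.frame(
    subject_id = summaries$subject_id,
    C_hat = capability_estimate(summaries$o_hat_D, summaries$T_hat_0),
    C0 = 1 / summaries$T_hat_0,
    T_hat_D = summaries$T_hat_D)
  glance <- glance_analysis(records, include_crashed = include_crashed)
  n_crashed <- sum(vapply(records, function(r) r$crashed, logical(1)))
  structure(list(summaries = summaries, comparison = comparison,
                 slope = slope, capability = capability, glance = glance,
                 exclusions = list(n_crashed = n_crashed,
                                   include_crashed = include_crashed)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("== analysis of %d subjects (%d crashed trials %s) ==\n",
              nrow(x$summaries), x$exclusions$n_crashed,
              if (x$exclusions$include_crashed) "included" else "excluded"))
  print(x$comparison)
  print(x$slope)
  print(x$glance)
  invisible(x)
}

# Serialise an analysis_report to plain lists for JSON output.
report_to_list <- function(report) {
  cmp <- report$comparison
  sl <- report$slope
  sg <- report$glance$signs
  list(
    n_subjects = cmp$n,
    correlations = list(
      r_indep = cmp$r_indep, ci_indep = cmp$ci_indep[c("low", "high")],
      r_rel = cmp$r_rel, ci_rel = cmp$ci_rel[c("low", "high")],
      r_overlap = cmp$r_overlap,
      diff = cmp$diff_ci[c("estimate", "low", "high")]),
    slope_fit = list(alpha = sl$alpha, alpha0 = sl$alpha0,
                     r_squared = sl$r_squared,
                     slope_ci = sl$slope_ci[c("low", "high")],
                     identity_line_inside = sl$identity_line_inside),
    sign_tests = sg,
    median_pb_slope = stats::median(report$glance$pb_fits$slope),
    exclusions = report$exclusions)
}

#' Load a run configuration from JSON
#'
#' The JSON object may contain `pop` (fields of [population_spec()]),
#' `params` (fields of [driver_params()]) and the scalar options the
#' pipeline entry points understand (`out_dir`, `data_dir`, `dt`,
#' `trial_length`, `include_crashed`, `pool`); every field is optional and
#' overrides the corresponding default.
#'
#' @param path Path to a JSON file.
#' @return A config list for [run_simulate()] / [run_analyze()].
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- raw
  cfg$pop <- do.call(population_spec, as.list(raw$pop %||% list()))
  cfg$params <- do.call(driver_params, as.list(raw$params %||% list()))
  cfg
}

#' Simulate and write a dataset (pipeline entry point)
#'
#' @param config List with optional elements `pop` ([population_spec()]),
#'   `params` ([driver_params()]), `out_dir`, `dt`, `trial_length`; or a
#'   path to a JSON file in the [load_config()] schema.
#' @return The simulated records, invisibly; logs are written when
#'   `out_dir` is set.
#' @export
run_simulate <- function(config = list()) {
  if (is.character(config)) config <- load_config(config)
  pop <- config$pop %||% population_spec()
  params <- config$params %||% driver_params()
  records <- simulate_experiment(pop, params,
                                 dt = config$dt %||% 0.01,
                                 trial_length = config$trial_length %||% 2000)
  n_crash <- sum(vapply(records, function(r) r$crashed, logical(1)))
  message(sprintf("simulated %d trials, %d crashed", length(records), n_crash))
  if (!is.null(config$out_dir)) write_trials(records, config$out_dir)
  invisible(records)
}

#' Analyse a dataset from disk or memory (pipeline entry point)
#'
#' @param config List with `data_dir` (read with [read_trials()]) or
#'   `records`; optional `out_dir` for the JSON report and CSV tables,
#'   `include_crashed`, `pool`. A character path is read with
#'   [load_config()].
#' @return The `analysis_report`, invisibly.
#' @export
run_analyze <- function(config = list()) {
  if (is.character(config)) config <- load_config(config)
  records <- config$records %||% read_trials(config$data_dir)
  report <- analyze_experiment(records,
                               include_crashed = isTRUE(config$include_crashed),
                               pool = config$pool %||% "samples")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(report$summaries,
                     file.path(config$out_dir, "subject_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(report$glance$trial_stats,
                     file.path(config$out_dir, "trial_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(report$glance$pb_fits,
                     file.path(config$out_dir, "pb_fits.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
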