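#' Robust detrending of a glance-onset signal
#'
#' Subtracts a Theil-Sen line fitted over glance-onset time, removing slow
#' within-trial drift in the preferred headway or glance interval so that
#' the residual covariation reflects short-timescale adaptation.
#'
#' @param t Glance-onset times, seconds (>= 2 distinct values).
#' @param y Signal at those onsets (headway or occlusion duration), seconds.
#' @return List with `residuals`, `slope`, `intercept`, `trend` (fitted
#'   values).
#' @export
robust_detrend <- function(t, y) {
  fit <- theil_sen(t, y)
  trend <- fit$intercept + fit$slope * t
  list(residuals = y - trend, slope = fit$slope, intercept = fit$intercept,
       trend = trend)
}

#' Detrend one trial's glance-onset pairs
#'
#' Applies [robust_detrend()] to both the instantaneous headway and the next
#' occlusion duration over glance-onset time, yielding the detrended pairs
#' `(T_d, o_d)` on which the within-trial covariation is measured.
#'
#' @param samples Data.frame from [glance_onset_samples()] (>= 2 rows).
#' @return List of class `detrended_pairs`: `t_g`, `T_d`, `o_d`, raw values,
#'   and the two trend fits.
#' @export
detrend_trial <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 2L)
  dT <- robust_detrend(samples$t_g, samples$T_at_onset)
  do <- robust_detrend(samples$t_g, samples$o_next)
  structure(list(t_g = samples$t_g, T_d = dT$residuals, o_d = do$residuals,
                 T_raw = samples$T_at_onset, o_raw = samples$o_next,
                 trend_T = dT[c("slope", "intercept")],
                 trend_o = do[c("slope", "intercept")]),
            class = "detrended_pairs")
}

#' Per-trial Spearman correlations of detrended pairs
#'
#' @param pairs_list List of `detrended_pairs` (one per occluded trial),
#'   each carrying `subject_id`/`trial_id` attributes or accompanied by the
#'   `ids` data.frame.
#' @param ids Optional data.frame with `subject_id`, `trial_id` aligned with
#'   `pairs_list`.
#' @param min_pairs Minimum glance pairs for a defined correlation
#'   (default 3); trials below it are flagged `used = FALSE`.
#' @return Data.frame: `subject_id`, `trial_id`, `n_pairs`, `rho`, `used`.
#' @export
per_trial_correlations <- function(pairs_list, ids = NULL, min_pairs = 3L) {
  rows <- lapply(seq_along(pairs_list), function(i) {
    p <- pairs_list[[i]]
    sid <- if (!is.null(ids)) ids$subject_id[i] else attr(p, "subject_id")
    tid <- if (!is.null(ids)) ids$trial_id[i] else attr(p, "trial_id")
    n <- length(p$T_d)
    usable <- n >= min_pairs &&
      length(unique(p$T_d)) > 1L && length(unique(p$o_d)) > 1L
    data.frame(subject_id = if (is.null(sid)) NA else sid,
               trial_id = if (is.null(tid)) NA else tid,
               n_pairs = n,
               rho = if (usable) spearman_rho(p$T_d, p$o_d) else NA_real_,
               used = usable)
  })
  do.call(rbind, rows)
}

#' Sign tests on per-trial correlations
#'
#' Trial level: the count of strictly positive detrended correlations over
#' all usable trials, with an exact two-sided binomial p-value at p0 = 0.5.
#' Subject level: the count of subjects whose median trial correlation is
#' strictly positive, tested the same way. Zero correlations count as
#' non-positive.
#'
#' @param trial_stats Data.frame from [per_trial_correlations()].
#' @return List: `k_trials`, `n_trials`, `p_trials`, `k_subjects`,
#'   `n_subjects`, `p_subjects`, `median_rho`, `median_subject_rho`.
#' @export
sign_tests <- function(trial_stats) {
  ts <- trial_stats[trial_stats$used, ]
  stopifnot(nrow(ts) >= 1L)
  k_trials <- sum(ts$rho > 0)
  n_trials <- nrow(ts)
  med_by_subj <- tapply(ts$rho, ts$subject_id, stats::median)
  k_subjects <- sum(med_by_subj > 0)
  n_subjects <- length(med_by_subj)
  list(k_trials = k_trials, n_trials = n_trials,
       p_trials = binom_test_exact(k_trials, n_trials, 0.5),
       k_subjects = k_subjects, n_subjects = n_subjects,
       p_subjects = binom_test_exact(k_subjects, n_subjects, 0.5),
       median_rho = stats::median(ts$rho),
       median_subject_rho = stats::median(med_by_subj))
}

#' Per-subject Passing-Bablok fit of detrended pairs
#'
#' Pools the detrended `(T_d, o_d)` pairs across one subject's occluded
#' trials and fits the symmetric Passing-Bablok line of `o_d` on `T_d`; the
#' slope estimates the glance-adaptation gain beta. For reporting in the
#' original-scale convention, the subject's median trends can be added back
#' via `trend_T_med`/`trend_o_med`.
#'
#' @param pairs_list List of `detrended_pairs` for one subject's occluded
#'   trials.
#' @param level Confidence level for the slope interval, default 0.95.
#' @param min_pairs Pools below this size are flagged `low_n` (default 10).
#' @return List of class `pb_fit`: `slope`, `intercept`, `slope_ci`,
#'   `n_pairs`, `n_slopes`, `low_n`, `trend_T_med`, `trend_o_med`.
#' @export
subject_pb_fit <- function(pairs_list, level = 0.95, min_pairs = 10L) {
  stopifnot(length(pairs_list) >= 1L)
  T_d <- unlist(lapply(pairs_list, `[[`, "T_d"))
  o_d <- unlist(lapply(pairs_list, `[[`, "o_d"))
  fit <- passing_bablok(T_d, o_d, level = level)
  med <- function(field, comp) {
    stats::median(vapply(pairs_list, function(p) p[[field]][[comp]],
                         numeric(1)))
  }
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 slope_ci = fit$slope_ci, n_pairs = fit$n_pairs,
                 n_slopes = fit$n_slopes, low_n = fit$n_pairs < min_pairs,
                 trend_T_med = list(slope = med("trend_T", "slope"),
                                    intercept = med("trend_T", "intercept")),
                 trend_o_med = list(slope = med("trend_o", "slope"),
                                    intercept = med("trend_o", "intercept"))),
            class = "pb_fit")
}

#' Full within-trial glance analysis of an experiment
#'
#' Builds glance-onset samples for every usable occluded trial, detrends
#' them, and returns per-trial correlations, the sign tests, and per-subject
#' Passing-Bablok fits.
#'
#' @param records List of `trial_record`s.
#' @param include_crashed Keep crashed trials (default FALSE).
#' @param min_pairs_trial Minimum glance pairs per trial (default 3).
#' @return List of class `glance_report`: `trial_stats` (data.frame),
#'   `signs` (from [sign_tests()]), `pb_fits` (data.frame with one row per
#'   subject), `n_trials_excluded`.
#' @export
glance_analysis <- function(records, include_crashed = FALSE,
                            min_pairs_trial = 3L) {
  occ <- Filter(function(r) {
    r$condition == "occluded" && (include_crashed || !r$crashed)
  }, records)
  n_excluded <- sum(vapply(records, function(r) {
    r$condition == "occluded" && !include_crashed && r$crashed
  }, logical(1)))
  pairs_list <- list()
  ids <- list()
  for (r in occ) {
    gs <- glance_onset_samples(r)
    if (nrow(gs) < 2L) next
    pairs_list <- c(pairs_list, list(detrend_trial(gs)))
    ids <- c(ids, list(data.frame(subject_id = r$subject_id,
                                  trial_id = r$trial_id)))
  }
  if (length(pairs_list) == 0L) stop("no usable occluded trials")
  ids <- do.call(rbind, ids)
  trial_stats <- per_trial_correlations(pairs_list, ids = ids,
                                        min_pairs = min_pairs_trial)
  signs <- sign_tests(trial_stats)
  pb_rows <- lapply(unique(ids$subject_id), function(s) {
    pl <- pairs_list[ids$subject_id == s]
    n_pairs <- sum(vapply(pl, function(p) length(p$T_d), integer(1)))
    if (n_pairs < 3L) return(NULL)
    fit <- subject_pb_fit(pl)
    data.frame(subject_id = s, slope = fit$slope, intercept = fit$intercept,
               slope_lo = fit$slope_ci$low, slope_hi = fit$slope_ci$high,
               n_pairs = fit$n_pairs, n_slopes = fit$n_slopes,
               low_n = fit$low_n)
  })
  structure(list(trial_stats = trial_stats, signs = signs,
                 pb_fits = do.call(rbind, Filter(Negate(is.null), pb_rows)),
                 n_trials_excluded = n_excluded),
            class = "glance_report")
}

#' @export
print.glance_report <- function(x, ...) {
  s <- x$signs
  cat(sprintf("%d of %d trials with positive detrended correlation (p = %.2g)\n",
              s$k_trials, s$n_trials, s$p_trials))
  cat(sprintf("%d of %d subjects with positive median correlation (p = %.2g)\n",
              s$k_subjects, s$n_subjects, s$p_subjects))
  cat(sprintf("median rho %.2f; median PB slope %.2f\n",
              s$median_rho, stats::median(x$pb_fits$slope)))
  invisible(x)
}
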