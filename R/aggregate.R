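#' Compare baseline-independent vs baseline-relative headway adaptation
#'
#' Computes the Spearman correlation of the per-subject headway increase with
#' the mean occlusion duration, `r_indep = rho(delta_T, o_hat_D)`, and of the
#' baseline-scaled increase, `r_rel = rho(delta_rel, o_hat_D)`; 95% intervals
#' by Fisher z with SE `1/sqrt(n-3)` applied to the Spearman coefficients,
#' and a confidence interval for `r_indep - r_rel` by Zou's method for
#' dependent overlapping correlations (the two share `o_hat_D`), with the
#' overlap correlation `rho(delta_T, delta_rel)` taken from the data. All
#' statistics operate on rank-transformed values.
#'
#' @param summaries Data.frame from [summarize_subjects()] (>= 4 rows).
#' @param level Confidence level, default 0.95.
#' @return List of class `correlation_comparison`: `r_indep`, `r_rel`,
#'   `ci_indep`, `ci_rel`, `r_overlap`, `diff_ci`, `n`.
#' @export
compare_models <- function(summaries, level = 0.95) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 4L)
  dT <- summaries$delta_T
  dR <- summaries$delta_rel
  o <- summaries$o_hat_D
  n <- nrow(summaries)
  r_indep <- spearman_rho(dT, o)
  r_rel <- spearman_rho(dR, o)
  r_overlap <- spearman_rho(dT, dR)
  structure(list(r_indep = r_indep, r_rel = r_rel,
                 ci_indep = fisher_z_ci(r_indep, n, level),
                 ci_rel = fisher_z_ci(r_rel, n, level),
                 r_overlap = r_overlap,
                 diff_ci = zou_diff_ci(r_indep, r_rel, r_overlap, n, level),
                 n = n),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("baseline-independent rho = %.2f (%.2f, %.2f)\n",
              x$r_indep, x$ci_indep$low, x$ci_indep$high))
  cat(sprintf("baseline-relative   rho = %.2f (%.2f, %.2f)\n",
              x$r_rel, x$ci_rel$low, x$ci_rel$high))
  cat(sprintf("difference %.3f, 95%% CI (%.3f, %.3f), n = %d\n",
              x$diff_ci$estimate, x$diff_ci$low, x$diff_ci$high, x$n))
  invisible(x)
}

#' Fit the headway-increase vs occlusion-duration slope
#'
#' Ordinary least squares of `delta_T` on `o_hat_D` across subjects, with
#' t-based 95% parameter intervals and a joint F-region test of the identity
#' line (slope 1, intercept 0): under one-to-one task-difficulty
#' homeostasis the headway increase equals the mean occlusion duration, and
#' `identity_line_inside` reports whether that cannot be rejected.
#'
#' @param summaries Data.frame from [summarize_subjects()] (>= 3 rows).
#' @param level Confidence level, default 0.95.
#' @return List of class `slope_fit`: `alpha` (slope), `alpha0` (intercept),
#'   `r_squared`, `slope_ci`, `intercept_ci`, `identity_line_inside`,
#'   `f_stat`, `n`.
#' @export
fit_headway_slope <- function(summaries, level = 0.95) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 3L)
  fit <- ols_fit(summaries$o_hat_D, summaries$delta_T, level = level,
                 slope0 = 1, intercept0 = 0)
  structure(list(alpha = fit$slope, alpha0 = fit$intercept,
                 r_squared = fit$r_squared, slope_ci = fit$slope_ci,
                 intercept_ci = fit$intercept_ci,
                 identity_line_inside = fit$inside, f_stat = fit$f_stat,
                 n = nrow(summaries)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("delta_T = %.3f * o_hat_D + %.3f  (R^2 = %.3f, n = %d)\n",
              x$alpha, x$alpha0, x$r_squared, x$n))
  cat(sprintf("slope CI (%.3f, %.3f); identity line inside joint region: %s\n",
              x$slope_ci$low, x$slope_ci$high, x$identity_line_inside))
  invisible(x)
}

#' Driver capability estimate
#'
#' Operationalizes average capability from the mean occlusion duration and
#' the undistracted headway: `C_hat = 1 / (o_hat + T_hat_0)` (1/s). With no
#' distraction this reduces to the base capability `C0 = 1 / T_hat_0`.
#'
#' @param o_hat Mean occlusion duration, seconds (>= 0).
#' @param T_hat_0 Unoccluded mean time headway, seconds (> 0).
#' @return Capability, 1/seconds (vectorised).
#' @export
capability_estimate <- function(o_hat, T_hat_0) {
  stopifnot(all(o_hat >= 0), all(T_hat_0 > 0))
  1 / (o_hat + T_hat_0)
}
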