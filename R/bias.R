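# Publication-bias diagnostics: Egger regression intercept test and
# funnel-plot coordinates.

#' Egger regression test for funnel-plot asymmetry
#'
#' The classic (unweighted) Egger test: ordinary least squares of the
#' standardized effect `theta_i/se_i` on the precision `1/se_i`. Under no
#' small-study effect the intercept is zero; a non-zero intercept signals
#' asymmetry consistent with publication bias. The test statistic is
#' `t = intercept / SE(intercept)` referred to a t distribution with
#' `k - 2` degrees of freedom (two-tailed).
#'
#' @param estimates List of [effect_estimate()] objects, `k >= 3`.
#' @return An object of class `egger_result` with components `intercept`,
#'   `intercept_se`, `slope`, `t_statistic`, `df`, `p_two_tailed`, `k`.
#' @examples
#' ests <- lapply(1:5, function(i)
#'   effect_estimate(0.5 + 0.1 * i, se = 0.1 * i, study_id = paste0("s", i)))
#' egger_test(ests)
#' @export
egger_test <- function(estimates) {
  estimates <- check_estimates(estimates)
  k <- length(estimates)
  if (k < 3)
    stop("Egger regression needs at least 3 studies (k - 2 >= 1 df)", call. = FALSE)
  th <- vapply(estimates, `[[`, numeric(1), "estimate")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  snd <- th / se
  prec <- 1 / se
  if (stats::sd(prec) == 0)
    stop("all standard errors identical: precision is constant and the regression design is degenerate",
         call. = FALSE)
  fit <- stats::lm(snd ~ prec)
  sm <- summary(fit)$coefficients
  intercept <- sm["(Intercept)", "Estimate"]
  intercept_se <- sm["(Intercept)", "Std. Error"]
  tstat <- intercept / intercept_se
  df <- k - 2L
  structure(
    list(intercept = intercept, intercept_se = intercept_se,
         slope = sm["prec", "Estimate"], t_statistic = tstat, df = df,
         p_two_tailed = 2 * stats::pt(-abs(tstat), df = df), k = k),
    class = "egger_result"
  )
}

#' Funnel-plot coordinates
#'
#' One point per study: the effect on its reporting scale (odds ratio for
#' log-OR input, exponentiated; mean differences pass through) against the
#' standard error. By convention the SE axis is drawn inverted (small SE,
#' i.e. large studies, at the top) and the OR axis log-spaced.
#'
#' @param estimates List of [effect_estimate()] objects, `k >= 1`.
#' @return A data frame with columns `study_id`, `effect`, `se`.
#' @export
funnel_coordinates <- function(estimates) {
  estimates <- check_estimates(estimates)
  th <- vapply(estimates, `[[`, numeric(1), "estimate")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  ids <- vapply(estimates, `[[`, character(1), "study_id")
  effect <- if (estimates[[1]]$scale == "log_odds_ratio") exp(th) else th
  data.frame(study_id = ids, effect = effect, se = se,
             stringsAsFactors = FALSE)
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger regression (k = %d, df = %d)\n", x$k, x$df))
  cat(sprintf("  intercept %.4f (SE %.4f), slope %.4f\n",
              x$intercept, x$intercept_se, x$slope))
  cat(sprintf("  t = %.3f, two-tailed p = %s\n",
              x$t_statistic, format.pval(x$p_two_tailed, digits = 3)))
  invisible(x)
}
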