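# Inverse-variance pooling: fixed effect and DerSimonian-Laird random effects,
# with Cochran's Q, tau^2, I^2 and the heterogeneity p-value.

check_estimates <- function(estimates) {
  if (length(estimates) == 0) stop("no estimates supplied", call. = FALSE)
  ok <- vapply(estimates, inherits, logical(1), what = "effect_estimate")
  if (!all(ok)) stop("all elements must be effect_estimate objects", call. = FALSE)
  scales <- vapply(estimates, `[[`, character(1), "scale")
  if (length(unique(scales)) > 1)
    stop("estimates mix analysis scales; pool log-ORs and mean differences separately",
         call. = FALSE)
  estimates
}

new_pooled_result <- function(pooled, se, ci_level, scale, k, q, tau2,
                              weights, method, study_ids, degenerate = FALSE) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  p_het <- if (k > 1) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  names(weights) <- study_ids
  structure(
    list(pooled_estimate = pooled, se = se,
         ci_low = pooled - z * se, ci_high = pooled + z * se,
         ci_level = ci_level, scale = scale, k = k,
         q = q, tau2 = tau2, i2_percent = i2, p_het = p_het,
         weights = weights, method = method, degenerate = degenerate),
    class = "pooled_result"
  )
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each study by the reciprocal of its sampling variance,
#' `w_i = 1/se_i^2`; the pooled estimate is `sum(w_i * theta_i) / sum(w_i)`
#' with `SE = 1/sqrt(sum(w_i))` and a z-based confidence interval.
#' Cochran's Q, I^2 and the heterogeneity p-value (chi-square, k-1 df) are
#' reported alongside; `tau2` is 0 by definition of the fixed-effect model.
#'
#' @param estimates List of [effect_estimate()] objects on one common scale.
#' @param ci_level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "fixed"`.
#' @export
pool_fixed <- function(estimates, ci_level = 0.95) {
  estimates <- check_estimates(estimates)
  th <- vapply(estimates, `[[`, numeric(1), "estimate")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  ids <- vapply(estimates, `[[`, character(1), "study_id")
  w <- 1 / se^2
  pooled <- sum(w * th) / sum(w)
  q <- sum(w * (th - pooled)^2)
  new_pooled_result(pooled, 1 / sqrt(sum(w)), ci_level,
                    estimates[[1]]$scale, length(th), q, tau2 = 0,
                    weights = w, method = "fixed", study_ids = ids,
                    degenerate = length(th) == 1)
}

#' DerSimonian-Laird random-effects pooling
#'
#' The moment estimator of between-study variance: with fixed-effect
#' weights `w_i = 1/se_i^2` and fixed-effect pooled mean `theta_F`,
#' `Q = sum(w_i (theta_i - theta_F)^2)` and
#' `tau2 = max(0, (Q - (k-1)) / (sum(w_i) - sum(w_i^2)/sum(w_i)))`.
#' Random-effects weights `w*_i = 1/(se_i^2 + tau2)` then give the pooled
#' estimate, its SE and a z-based confidence interval.
#' `I2 = max(0, (Q - (k-1))/Q) * 100` (0 when Q = 0) and the heterogeneity
#' p-value is the upper chi-square tail at Q with k-1 df.
#'
#' A single study is returned unchanged with Q = tau2 = I2 = 0 and the
#' `degenerate` flag set, rather than erroring, so pipelines that pool per
#' variant stay robust.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` with `method = "dersimonian_laird"`.
#' @examples
#' ests <- list(effect_estimate(0, 0.2, study_id = "a"),
#'              effect_estimate(1, 0.2, study_id = "b"),
#'              effect_estimate(2, 0.2, study_id = "c"))
#' pool_dl(ests)
#' @export
pool_dl <- function(estimates, ci_level = 0.95) {
  estimates <- check_estimates(estimates)
  th <- vapply(estimates, `[[`, numeric(1), "estimate")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  ids <- vapply(estimates, `[[`, character(1), "study_id")
  k <- length(th)
  if (k == 1) {
    return(new_pooled_result(th, se, ci_level, estimates[[1]]$scale, 1,
                             q = 0, tau2 = 0, weights = 1 / se^2,
                             method = "dersimonian_laird", study_ids = ids,
                             degenerate = TRUE))
  }
  w <- 1 / se^2
  fixed <- sum(w * th) / sum(w)
  q <- sum(w * (th - fixed)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * th) / sum(ws)
  new_pooled_result(pooled, 1 / sqrt(sum(ws)), ci_level,
                    estimates[[1]]$scale, k, q, tau2,
                    weights = ws, method = "dersimonian_laird",
                    study_ids = ids)
}

#' Exponentiate a log-odds-ratio pooled result to the OR scale
#'
#' @param r A `pooled_result` on the log-odds-ratio scale.
#' @return A list with components `or`, `or_ci_low`, `or_ci_high`.
#' @export
exponentiate_result <- function(r) {
  stopifnot(inherits(r, "pooled_result"))
  if (r$scale != "log_odds_ratio")
    stop("exponentiation only applies to log-odds-ratio results", call. = FALSE)
  list(or = exp(r$pooled_estimate),
       or_ci_low = exp(r$ci_low), or_ci_high = exp(r$ci_high))
}

#' Is between-study heterogeneity statistically significant?
#'
#' Strict comparison of the heterogeneity p-value against `alpha`
#' (`p_het < alpha`); at the boundary the verdict is `FALSE`.
#'
#' @param r A `pooled_result`.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE`/`FALSE` (`NA` for a single-study result).
#' @export
heterogeneity_significant <- function(r, alpha = 0.05) {
  stopifnot(inherits(r, "pooled_result"))
  if (is.na(r$p_het)) return(NA)
  r$p_het < alpha
}

#' @export
print.pooled_result <- function(x, digits = 2, ...) {
  meth <- if (x$method == "fixed") "fixed-effect" else "DerSimonian-Laird random-effects"
  cat(sprintf("%s pooling of %d studies (%s scale)\n", meth, x$k, x$scale))
  if (x$scale == "log_odds_ratio") {
    cat(sprintf("  OR %.*f (%.0f%% CI %.*f-%.*f)\n", digits,
                exp(x$pooled_estimate), 100 * x$ci_level,
                digits, exp(x$ci_low), digits, exp(x$ci_high)))
  } else {
    cat(sprintf("  MD %.*f (%.0f%% CI %.*f-%.*f)\n", digits,
                x$pooled_estimate, 100 * x$ci_level,
                digits, x$ci_low, digits, x$ci_high))
  }
  cat(sprintf("  Q = %.*f, tau^2 = %.*f, I^2 = %.0f%%, p_het = %s\n",
              digits, x$q, max(digits, 3), x$tau2, x$i2_percent,
              if (is.na(x$p_het)) "NA" else format.pval(x$p_het, digits = 2)))
  if (isTRUE(x$degenerate)) cat("  (single study: pass-through, no pooling)\n")
  invisible(x)
}
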