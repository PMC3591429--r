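# Mean-difference to odds-ratio conversion via the logistic-distribution
# identity (Hasselblad-Hedges): ln OR = d * pi/sqrt(3), d = MD/SD.

LOGISTIC_SCALE <- pi / sqrt(3)

#' Convert a mean difference on a biomarker into an odds ratio
#'
#' Standardizes the mean difference by the pooled within-group SD,
#' `d = MD/sd_pooled`, and maps it to the log odds ratio through the
#' logistic identity `ln OR = d * pi/sqrt(3)`. This is the conversion
#' standard meta-analysis software applies when a continuous case-control
#' difference has to be expressed as an odds ratio. If the standard error
#' of the mean difference is supplied, the log-OR standard error is scaled
#' the same way, giving a confidence interval on the OR scale.
#'
#' No small-sample (Hedges) correction is applied by default, since the
#' input is usually an already-pooled summary; supply `hedges_df` (the
#' degrees of freedom `n1 + n2 - 2`) to shrink `d` by
#' `1 - 3/(4*df - 1)` first.
#'
#' @param mean_difference Mean difference (e.g. micromol/L homocysteine).
#' @param sd_pooled Positive pooled within-group SD, same units.
#' @param se_md Optional standard error of the mean difference.
#' @param ci_level Confidence level for the CI when `se_md` is given.
#' @param hedges_df Optional degrees of freedom for the Hedges
#'   small-sample correction; `NULL` (default) applies none.
#' @return A list with `or`, `log_or`, `d`, and — when `se_md` is given —
#'   `log_or_se`, `or_ci_low`, `or_ci_high`.
#' @examples
#' md_to_or(2.90, sd_pooled = 10.1, se_md = 1.25)
#' @export
md_to_or <- function(mean_difference, sd_pooled, se_md = NULL,
                     ci_level = 0.95, hedges_df = NULL) {
  if (!is.finite(sd_pooled) || sd_pooled <= 0)
    stop("`sd_pooled` must be positive", call. = FALSE)
  d <- mean_difference / sd_pooled
  j <- 1
  if (!is.null(hedges_df)) {
    if (hedges_df <= 1) stop("`hedges_df` must exceed 1", call. = FALSE)
    j <- 1 - 3 / (4 * hedges_df - 1)
  }
  log_or <- j * d * LOGISTIC_SCALE
  out <- list(or = exp(log_or), log_or = log_or, d = j * d)
  if (!is.null(se_md)) {
    if (!is.finite(se_md) || se_md <= 0)
      stop("`se_md` must be positive", call. = FALSE)
    log_or_se <- j * (se_md / sd_pooled) * LOGISTIC_SCALE
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    out$log_or_se <- log_or_se
    out$or_ci_low <- exp(log_or - z * log_or_se)
    out$or_ci_high <- exp(log_or + z * log_or_se)
  }
  out
}

#' Invert the logistic OR conversion back to a mean difference
#'
#' `MD = ln(OR) * sqrt(3)/pi * sd_pooled`; the exact inverse of
#' [md_to_or()], useful for consistency checks such as back-solving the
#' pooled SD implied by a published (MD, OR) pair.
#'
#' @param or Positive odds ratio.
#' @param sd_pooled Positive pooled within-group SD.
#' @return The mean difference on the original units.
#' @export
or_to_md <- function(or, sd_pooled) {
  if (!is.finite(or) || or <= 0) stop("`or` must be positive", call. = FALSE)
  if (!is.finite(sd_pooled) || sd_pooled <= 0)
    stop("`sd_pooled` must be positive", call. = FALSE)
  log(or) / LOGISTIC_SCALE * sd_pooled
}
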