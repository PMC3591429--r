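# Literature-based Mendelian randomization: scale a biomarker-disease odds
# ratio by the genotype-biomarker effect (log-linear dose assumption) to get
# the expected genetic odds ratio, build its CI from count reciprocals, and
# compare with the observed genetic odds ratio.

#' Inputs for the expected-OR Mendelian randomization calculation
#'
#' @param or_biomarker_disease Odds ratio of disease associated with a
#'   `md_case_control` difference in the biomarker (e.g. 1.68 per
#'   2.90 micromol/L homocysteine).
#' @param md_case_control The biomarker mean difference (same units as
#'   `delta_x`) to which `or_biomarker_disease` corresponds; non-zero.
#' @param delta_x Mean biomarker difference conferred by the genotype
#'   contrast (e.g. TT vs CC) in healthy subjects.
#' @param frequencies Positive integer counts whose reciprocals are summed
#'   to form the squared standard error of the expected log OR. The choice
#'   of counts (case/control totals, genotype-class totals, ...) is the
#'   analyst's and is deliberately explicit.
#' @param ci_z Normal quantile for the CI half-width; fixed by convention
#'   at 1.96 for a 95% interval.
#' @return An object of class `mr_inputs`.
#' @examples
#' mr_inputs(1.68, 2.90, 5.18, frequencies = c(309, 356))
#' @export
mr_inputs <- function(or_biomarker_disease, md_case_control, delta_x,
                      frequencies, ci_z = 1.96) {
  if (!is.finite(or_biomarker_disease) || or_biomarker_disease <= 0)
    stop("`or_biomarker_disease` must be positive", call. = FALSE)
  if (!is.finite(md_case_control) || md_case_control == 0)
    stop("`md_case_control` must be non-zero", call. = FALSE)
  check_frequencies(frequencies)
  structure(list(or_biomarker_disease = or_biomarker_disease,
                 md_case_control = md_case_control, delta_x = delta_x,
                 frequencies = frequencies, ci_z = ci_z),
            class = "mr_inputs")
}

check_frequencies <- function(frequencies) {
  if (length(frequencies) == 0)
    stop("`frequencies` must be non-empty", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies < 1))
    stop("all frequencies must be counts >= 1", call. = FALSE)
  invisible(frequencies)
}

#' Expected genetic odds ratio under log-linearity
#'
#' Scales the biomarker-disease odds ratio to the biomarker shift the
#' genotype confers: `exp(ln(OR) * delta_x / md_case_control)`. Under a
#' log-linear dose-response, an OR of 1.68 per 2.90 micromol/L implies
#' `exp(ln 1.68 * 5.18/2.90) = 2.53` per 5.18 micromol/L (the classic
#' worked example; published reports that round intermediates print 2.52).
#'
#' @param m An [mr_inputs()] object.
#' @return The expected odds ratio (full precision; round only to report).
#' @examples
#' expected_or(mr_inputs(1.68, 2.90, 5.18, frequencies = c(309, 356)))
#' @export
expected_or <- function(m) {
  stopifnot(inherits(m, "mr_inputs"))
  exp(log(m$or_biomarker_disease) * m$delta_x / m$md_case_control)
}

#' Confidence interval for the expected odds ratio
#'
#' `SE = sqrt(sum(1/f_i))` over the supplied counts; the interval is
#' `exp(ln(expected) -/+ z * SE)`, i.e. the antilogs of the log-scale
#' limits `ln(OR) +/- z*SE`.
#'
#' @param expected Positive expected odds ratio.
#' @param frequencies Positive integer counts (see [mr_inputs()]).
#' @param z Normal quantile (default 1.96).
#' @return A list with `low`, `high` and `se` (the log-scale SE).
#' @export
expected_or_ci <- function(expected, frequencies, z = 1.96) {
  if (!is.finite(expected) || expected <= 0)
    stop("`expected` must be positive", call. = FALSE)
  check_frequencies(frequencies)
  se <- sqrt(sum(1 / frequencies))
  list(low = exp(log(expected) - z * se),
       high = exp(log(expected) + z * se),
       se = se)
}

check_interval <- function(low, high, what) {
  if (low > high)
    stop(sprintf("%s interval is unordered (low > high)", what), call. = FALSE)
}

#' Is one confidence interval entirely inside another?
#'
#' Closed-interval convention: touching bounds count as contained.
#'
#' @param inner_low,inner_high The candidate inner interval.
#' @param outer_low,outer_high The outer interval.
#' @return `TRUE` iff `outer_low <= inner_low` and `inner_high <= outer_high`.
#' @export
ci_contained <- function(inner_low, inner_high, outer_low, outer_high) {
  check_interval(inner_low, inner_high, "inner")
  check_interval(outer_low, outer_high, "outer")
  outer_low <= inner_low && inner_high <= outer_high
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval convention: intervals touching at a single point overlap.
#'
#' @param a_low,a_high First interval.
#' @param b_low,b_high Second interval.
#' @return `TRUE` iff `a_low <= b_high` and `b_low <= a_high`.
#' @export
ci_overlap <- function(a_low, a_high, b_low, b_high) {
  check_interval(a_low, a_high, "first")
  check_interval(b_low, b_high, "second")
  a_low <= b_high && b_low <= a_high
}

#' Run the full expected-vs-observed Mendelian randomization comparison
#'
#' Composes [expected_or()] and [expected_or_ci()], and — when an observed
#' pooled genetic result is supplied — exponentiates it and reports whether
#' the observed CI falls entirely within the expected CI
#' ([ci_contained()]) and whether the two intervals overlap at all
#' ([ci_overlap()]). All internals are kept at full precision; the print
#' method rounds to 2 decimals.
#'
#' @param m An [mr_inputs()] object.
#' @param observed Optional `pooled_result` on the log-odds-ratio scale
#'   (the observed genotype-disease meta-analysis).
#' @return An object of class `mr_result`.
#' @examples
#' m <- mr_inputs(1.68, 2.90, 5.18, frequencies = c(1, 7))
#' run_mr(m)
#' @export
run_mr <- function(m, observed = NULL) {
  stopifnot(inherits(m, "mr_inputs"))
  exp_or <- expected_or(m)
  ci <- expected_or_ci(exp_or, m$frequencies, z = m$ci_z)
  res <- list(expected_or = exp_or,
              expected_ci_low = ci$low, expected_ci_high = ci$high,
              expected_se = ci$se,
              observed_or = NULL, observed_ci_low = NULL,
              observed_ci_high = NULL, contained = NULL, overlaps = NULL)
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "pooled_result"))
    obs <- exponentiate_result(observed)
    res$observed_or <- obs$or
    res$observed_ci_low <- obs$or_ci_low
    res$observed_ci_high <- obs$or_ci_high
    res$contained <- ci_contained(obs$or_ci_low, obs$or_ci_high,
                                  ci$low, ci$high)
    res$overlaps <- ci_overlap(obs$or_ci_low, obs$or_ci_high,
                               ci$low, ci$high)
  }
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 2, ...) {
  cat("Mendelian randomization: expected vs observed genetic odds ratio\n")
  cat(sprintf("  expected OR %.*f (95%% CI %.*f-%.*f; log-scale SE %.3f)\n",
              digits, x$expected_or, digits, x$expected_ci_low,
              digits, x$expected_ci_high, x$expected_se))
  if (!is.null(x$observed_or)) {
    cat(sprintf("  observed OR %.*f (95%% CI %.*f-%.*f)\n",
                digits, x$observed_or, digits, x$observed_ci_low,
                digits, x$observed_ci_high))
    cat(sprintf("  observed CI within expected CI: %s; CIs overlap: %s\n",
                x$contained, x$overlaps))
  } else {
    cat("  (no observed genetic meta-analysis supplied)\n")
  }
  invisible(x)
}
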