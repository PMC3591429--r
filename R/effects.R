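# Per-study effect estimates from raw summary data: genotype contrasts,
# 2x2-table odds ratios, mean differences, and Hozo median/range conversion.

#' Genotype counts for one case-control study
#'
#' Container for the raw genotype frequency table of a single study:
#' counts of homozygous-reference, heterozygous and homozygous-variant
#' subjects among cases and among controls.
#'
#' @param study_id Character study label.
#' @param gene Gene symbol (e.g. `"MTHFR"`).
#' @param variant Variant label (e.g. `"C677T"`).
#' @param case_counts,control_counts Numeric vectors of length 3 with names
#'   `ref`, `het`, `hom`: non-negative integer counts of homozygous-reference,
#'   heterozygous and homozygous-variant subjects.
#'
#' @return An object of class `genotype_counts`.
#' @examples
#' genotype_counts("study1", "MTHFR", "C677T",
#'                 case_counts    = c(ref = 50, het = 30, hom = 20),
#'                 control_counts = c(ref = 60, het = 30, hom = 10))
#' @export
genotype_counts <- function(study_id, gene, variant, case_counts, control_counts) {
  case_counts <- check_counts(case_counts, "case_counts")
  control_counts <- check_counts(control_counts, "control_counts")
  structure(
    list(study_id = as.character(study_id), gene = as.character(gene),
         variant = as.character(variant),
         case_counts = case_counts, control_counts = control_counts),
    class = "genotype_counts"
  )
}

check_counts <- function(x, what) {
  if (!all(c("ref", "het", "hom") %in% names(x)))
    stop(sprintf("`%s` must have names 'ref', 'het', 'hom'", what), call. = FALSE)
  x <- x[c("ref", "het", "hom")]
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop(sprintf("`%s` must be non-negative integers", what), call. = FALSE)
  if (sum(x) == 0)
    stop(sprintf("`%s` must have at least one non-zero genotype class", what),
         call. = FALSE)
  x
}

#' A 2x2 exposure-by-disease table
#'
#' The canonical intermediate between genotype counts and an odds ratio.
#' Cells are stored as reals so that continuity-corrected tables can be
#' represented; raw input counts are validated upstream as integers.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative cell counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(exposed_cases, unexposed_cases,
                       exposed_controls, unexposed_controls) {
  cells <- c(exposed_cases = exposed_cases, unexposed_cases = unexposed_cases,
             exposed_controls = exposed_controls,
             unexposed_controls = unexposed_controls)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("all cells of a 2x2 table must be finite and non-negative", call. = FALSE)
  if (sum(cells) <= 0)
    stop("2x2 table total must be positive", call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

#' A per-study effect estimate with its standard error
#'
#' @param estimate Point estimate on the analysis scale.
#' @param se Positive, finite standard error.
#' @param scale `"log_odds_ratio"` or `"mean_difference"`.
#' @param study_id Character study label.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(estimate, se,
                            scale = c("log_odds_ratio", "mean_difference"),
                            study_id = "") {
  scale <- match.arg(scale)
  if (!is.finite(estimate)) stop("`estimate` must be finite", call. = FALSE)
  if (!is.finite(se) || se <= 0)
    stop("`se` must be positive and finite", call. = FALSE)
  structure(list(estimate = estimate, se = se, scale = scale,
                 study_id = as.character(study_id)),
            class = "effect_estimate")
}

#' Summary of one study arm (n, mean, SD)
#'
#' For plasma homocysteine the units are micromol/L. `provenance` records
#' whether the mean/SD were reported directly or estimated from a
#' median/range summary via [hozo_mean_sd()].
#'
#' @param n Number of subjects (>= 1; >= 2 when the SD is reported).
#' @param mean Arm mean.
#' @param sd Arm standard deviation (>= 0).
#' @param provenance `"reported"` or `"hozo_estimated"`.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(n, mean, sd, provenance = c("reported", "hozo_estimated")) {
  provenance <- match.arg(provenance)
  if (!is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (provenance == "reported" && n < 2)
    stop("a reported SD requires n >= 2", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 provenance = provenance),
            class = "arm_summary")
}

#' Median/range summary of one study arm
#'
#' @param n Number of subjects.
#' @param median,min,max Reported median, minimum and maximum
#'   (`min <= median <= max`).
#' @return An object of class `median_range_summary`.
#' @export
median_range_summary <- function(n, median, min, max) {
  if (!is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (min > max) stop("`min` must not exceed `max`", call. = FALSE)
  if (median < min || median > max)
    stop("`median` must lie within [min, max]", call. = FALSE)
  structure(list(n = as.integer(n), median = median, min = min, max = max),
            class = "median_range_summary")
}

#' Collapse genotype counts to a 2x2 table under a genetic model
#'
#' Under the recessive model homozygous-variant carriers are the exposed
#' class and homozygous-reference the unexposed class; heterozygotes are
#' excluded (the TT-vs-CC style contrast). Under the dominant model
#' heterozygotes join the exposed class. Under the allelic model alleles,
#' not subjects, are counted: each homozygote contributes two alleles of
#' its kind and each heterozygote one of each.
#'
#' @param counts A [genotype_counts()] object.
#' @param model `"recessive"`, `"dominant"` or `"allelic"`.
#' @return A [two_by_two()] table.
#' @examples
#' gc <- genotype_counts("s1", "MTHFR", "C677T",
#'                       c(ref = 50, het = 30, hom = 20),
#'                       c(ref = 60, het = 30, hom = 10))
#' genotype_contrast(gc, "recessive")
#' @export
genotype_contrast <- function(counts, model = c("recessive", "dominant", "allelic")) {
  stopifnot(inherits(counts, "genotype_counts"))
  model <- match.arg(model)
  ca <- counts$case_counts
  co <- counts$control_counts
  switch(model,
    recessive = two_by_two(ca[["hom"]], ca[["ref"]], co[["hom"]], co[["ref"]]),
    dominant  = two_by_two(ca[["hom"]] + ca[["het"]], ca[["ref"]],
                           co[["hom"]] + co[["het"]], co[["ref"]]),
    allelic   = two_by_two(2 * ca[["hom"]] + ca[["het"]],
                           2 * ca[["ref"]] + ca[["het"]],
                           2 * co[["hom"]] + co[["het"]],
                           2 * co[["ref"]] + co[["het"]])
  )
}

not_estimable <- function(msg) {
  stop(structure(class = c("mrpool_not_estimable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Log odds ratio with standard error from a 2x2 table
#'
#' Computes the Woolf log odds ratio `ln(ad/bc)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. When an entire exposure row or
#' disease column is zero the odds ratio is not estimable and a condition
#' of class `mrpool_not_estimable` is signalled regardless of policy
#' (the situation of a variant absent from every subject). Otherwise, a
#' single zero cell is handled per `zero_policy`: `"haldane"` adds 0.5 to
#' all four cells (Haldane-Anscombe), `"not_estimable"` refuses.
#'
#' @param table A [two_by_two()] table.
#' @param zero_policy `"haldane"` or `"not_estimable"`.
#' @param study_id Study label carried into the result.
#' @return An [effect_estimate()] on the log-odds-ratio scale.
#' @examples
#' or_from_table(two_by_two(10, 90, 5, 95))
#' @export
or_from_table <- function(table, zero_policy = c("haldane", "not_estimable"),
                          study_id = "") {
  stopifnot(inherits(table, "two_by_two"))
  zero_policy <- match.arg(zero_policy)
  a <- table$exposed_cases;    b <- table$unexposed_cases
  c <- table$exposed_controls; d <- table$unexposed_controls
  if (a + c == 0 || b + d == 0)
    not_estimable("an entire exposure row is zero; odds ratio not estimable")
  if (a + b == 0 || c + d == 0)
    not_estimable("an entire disease column is zero; odds ratio not estimable")
  if (any(c(a, b, c, d) == 0)) {
    if (zero_policy == "not_estimable")
      not_estimable("zero cell and zero_policy = 'not_estimable'")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  effect_estimate(log((a * d) / (b * c)),
                  sqrt(1 / a + 1 / b + 1 / c + 1 / d),
                  scale = "log_odds_ratio", study_id = study_id)
}

#' Mean difference between two study arms
#'
#' `arm1 - arm2` with `SE = sqrt(sd1^2/n1 + sd2^2/n2)`, the building block
#' of continuous-outcome inverse-variance pooling.
#'
#' @param arm1,arm2 [arm_summary()] objects (e.g. cases and controls, or
#'   TT and CC genotype carriers).
#' @param study_id Study label carried into the result.
#' @return An [effect_estimate()] on the mean-difference scale.
#' @export
md_from_arms <- function(arm1, arm2, study_id = "") {
  stopifnot(inherits(arm1, "arm_summary"), inherits(arm2, "arm_summary"))
  se <- sqrt(arm1$sd^2 / arm1$n + arm2$sd^2 / arm2$n)
  if (se == 0)
    stop("both arms have zero SD: degenerate variance, mean difference has no standard error",
         call. = FALSE)
  effect_estimate(arm1$mean - arm2$mean, se,
                  scale = "mean_difference", study_id = study_id)
}

#' Estimate mean and SD from a median/range summary (Hozo method)
#'
#' Sample-size-dependent estimators for studies that report only a median
#' with minimum and maximum:
#' * mean: `(min + 2*median + max)/4` for `n <= 25`, the median otherwise;
#' * SD: `sqrt(((min - 2*median + max)^2/4 + (max - min)^2)/12)` for
#'   `n <= 15`, `range/4` for `15 < n <= 70`, `range/6` for `n > 70`.
#'
#' @param s A [median_range_summary()].
#' @return A list with components `mean` and `sd`.
#' @examples
#' hozo_mean_sd(median_range_summary(50, median = 3, min = 1, max = 5))
#' @export
hozo_mean_sd <- function(s) {
  stopifnot(inherits(s, "median_range_summary"))
  n <- s$n; a <- s$min; m <- s$median; b <- s$max
  mean <- if (n <= 25) (a + 2 * m + b) / 4 else m
  sd <- if (n <= 15) {
    sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  } else if (n <= 70) {
    (b - a) / 4
  } else {
    (b - a) / 6
  }
  list(mean = mean, sd = sd)
}

#' Convert a median/range summary into an arm summary
#'
#' Applies [hozo_mean_sd()] and tags the result `provenance = "hozo_estimated"`.
#'
#' @param s A [median_range_summary()].
#' @return An [arm_summary()].
#' @export
arm_from_median_range <- function(s) {
  est <- hozo_mean_sd(s)
  arm_summary(s$n, est$mean, est$sd, provenance = "hozo_estimated")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: %.4f (SE %.4f, %s)\n",
              if (nzchar(x$study_id)) x$study_id else "(unnamed)",
              x$estimate, x$se, x$scale))
  invisible(x)
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$exposed_cases, x$unexposed_cases,
                x$exposed_controls, x$unexposed_controls),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}
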