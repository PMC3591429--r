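# Synthetic-data generator: multi-study case-control genotype counts under
# Hardy-Weinberg equilibrium with a per-study log-OR drawn from a normal
# between-study distribution, and genotype-stratified normal biomarker levels.

#' Configuration of the synthetic-data generator
#'
#' The defaults describe a candidate-gene meta-analysis of the scale the
#' package targets: a true recessive odds ratio of 2.5 with between-study
#' SD tau = 0.2 on the log scale, 10 studies of 100-500 cases and 100-500
#' controls each, a risk-allele frequency of 0.30 (so both homozygote
#' classes are populated at these study sizes), and a homocysteine-like
#' biomarker: CC-genotype mean 10 micromol/L, SD 6 micromol/L, and a
#' TT-vs-CC genotype difference of 5.18 micromol/L.
#'
#' @param true_log_or True mean log odds ratio across studies.
#' @param tau Between-study SD of the log odds ratio (>= 0).
#' @param k Number of studies (>= 1).
#' @param n_cases_range,n_controls_range Integer ranges `c(lo, hi)` from
#'   which per-study sample sizes are drawn uniformly.
#' @param risk_allele_freq Risk (variant) allele frequency in (0, 1).
#' @param model Genetic model used to impose the odds ratio:
#'   `"recessive"`, `"dominant"` or `"allelic"`.
#' @param delta_x True genotype biomarker difference (micromol/L).
#' @param biomarker_mean_cc Biomarker mean in the reference (CC) genotype.
#' @param biomarker_sd Within-genotype biomarker SD (> 0).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(true_log_or = log(2.5), tau = 0.2, k = 10,
                       n_cases_range = c(100, 500),
                       n_controls_range = c(100, 500),
                       risk_allele_freq = 0.3,
                       model = c("recessive", "dominant", "allelic"),
                       delta_x = 5.18, biomarker_mean_cc = 10,
                       biomarker_sd = 6, seed = 1L) {
  model <- match.arg(model)
  stopifnot(tau >= 0, k >= 1, length(n_cases_range) == 2,
            length(n_controls_range) == 2,
            n_cases_range[1] <= n_cases_range[2],
            n_controls_range[1] <= n_controls_range[2],
            n_cases_range[1] >= 1, n_controls_range[1] >= 1,
            risk_allele_freq > 0, risk_allele_freq < 1,
            biomarker_sd > 0)
  structure(list(true_log_or = true_log_or, tau = tau, k = as.integer(k),
                 n_cases_range = as.integer(n_cases_range),
                 n_controls_range = as.integer(n_controls_range),
                 risk_allele_freq = risk_allele_freq, model = model,
                 delta_x = delta_x, biomarker_mean_cc = biomarker_mean_cc,
                 biomarker_sd = biomarker_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Derived per-study substream seed: adding studies never perturbs the
# streams of earlier ones. Kept below 2^31 - 1.
substream_seed <- function(seed, i, salt = 0L) {
  (abs(seed) * 48271 + i * 7919 + salt * 104729) %% 2147483629
}

# sample() treats a length-1 vector as 1:x, so collapse degenerate ranges
sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

hwe_probs <- function(q) {
  p <- 1 - q
  c(ref = p^2, het = 2 * p * q, hom = q^2)
}

case_probs <- function(ctrl, theta, model) {
  w <- switch(model,
    recessive = c(1, 1, exp(theta)),
    dominant  = c(1, exp(theta), exp(theta)),
    allelic   = c(1, exp(theta), exp(2 * theta)))
  pr <- ctrl * w
  if (any(!is.finite(pr)) || sum(pr) <= 0)
    stop("degenerate case genotype probabilities", call. = FALSE)
  pr / sum(pr)
}

#' Simulate genotype counts for a multi-study meta-analysis
#'
#' For study i, a study-specific log odds ratio `theta_i` is drawn from
#' `Normal(true_log_or, tau^2)`. Control genotype probabilities follow
#' Hardy-Weinberg equilibrium at the risk-allele frequency; case
#' probabilities reweight the exposed genotype class(es) by `exp(theta_i)`
#' (by `exp(2 theta_i)` for variant homozygotes under the allelic model)
#' and renormalize, so the within-study odds ratio of the model's contrast
#' is exactly `exp(theta_i)`. Genotype counts are multinomial draws at the
#' study's sampled case and control sizes.
#'
#' @param cfg A [sim_config()].
#' @return A list of `k` [genotype_counts()] objects.
#' @examples
#' studies <- simulate_genotype_meta(sim_config(k = 3, seed = 7))
#' @export
simulate_genotype_meta <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ctrl_pr <- hwe_probs(cfg$risk_allele_freq)
  lapply(seq_len(cfg$k), function(i) {
    set.seed(substream_seed(cfg$seed, i))
    theta <- stats::rnorm(1, cfg$true_log_or, cfg$tau)
    n_ca <- sample_range(cfg$n_cases_range)
    n_co <- sample_range(cfg$n_controls_range)
    ca_pr <- case_probs(ctrl_pr, theta, cfg$model)
    ca <- stats::rmultinom(1, n_ca, ca_pr)[, 1]
    co <- stats::rmultinom(1, n_co, ctrl_pr)[, 1]
    names(ca) <- names(co) <- c("ref", "het", "hom")
    genotype_counts(sprintf("sim%02d", i), "SIMGENE", "simvar", ca, co)
  })
}

#' Simulate genotype-stratified biomarker arm summaries
#'
#' Draws biomarker values `Normal(biomarker_mean_cc, sd^2)` for the
#' reference (CC) arm and `Normal(biomarker_mean_cc + delta_x, sd^2)` for
#' the variant-homozygote (TT) arm, and returns the two sample summaries —
#' the raw material of a genotype-biomarker mean-difference study.
#'
#' @param cfg A [sim_config()].
#' @param n_tt,n_cc Arm sizes (>= 2).
#' @param study Integer study index selecting the RNG substream.
#' @return A list with components `tt` and `cc`, both [arm_summary()].
#' @export
simulate_biomarker_by_genotype <- function(cfg, n_tt, n_cc, study = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_tt < 2 || n_cc < 2)
    stop("arm sizes must be at least 2", call. = FALSE)
  set.seed(substream_seed(cfg$seed, study, salt = 1L))
  tt <- stats::rnorm(n_tt, cfg$biomarker_mean_cc + cfg$delta_x, cfg$biomarker_sd)
  cc <- stats::rnorm(n_cc, cfg$biomarker_mean_cc, cfg$biomarker_sd)
  list(tt = arm_summary(n_tt, mean(tt), stats::sd(tt)),
       cc = arm_summary(n_cc, mean(cc), stats::sd(cc)))
}

#' Simulate a median/range arm summary
#'
#' Draws `n` normal biomarker values and reports only their median,
#' minimum and maximum — the reporting style that forces the Hozo
#' conversion ([hozo_mean_sd()]) downstream.
#'
#' @param cfg A [sim_config()].
#' @param n Sample size (>= 3).
#' @param study Integer study index selecting the RNG substream.
#' @return A [median_range_summary()].
#' @export
simulate_median_range <- function(cfg, n, study = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n < 3) stop("`n` must be at least 3", call. = FALSE)
  set.seed(substream_seed(cfg$seed, study, salt = 2L))
  x <- stats::rnorm(n, cfg$biomarker_mean_cc, cfg$biomarker_sd)
  median_range_summary(n, stats::median(x), min(x), max(x))
}
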