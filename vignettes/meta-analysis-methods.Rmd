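---
title: "Methods: pooling genetic association studies and the expected-OR Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling genetic association studies and the expected-OR Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpool)
```

## The problem

Candidate-gene studies of a disease such as ischemic stroke report, per
study, how many cases and controls carry each genotype of a variant.
Individually these studies are small and noisy; the analysis that makes
them informative is (i) a random-effects meta-analysis of the per-study
odds ratios, with heterogeneity and publication-bias diagnostics, and
(ii) — when the variant acts through a measurable biomarker, as MTHFR
C677T acts through plasma homocysteine — a literature-based Mendelian
randomization: the genotype is a lifelong, confounder-free "randomized
exposure" to a higher biomarker level, so the odds ratio *expected* from
the biomarker-disease association can be compared with the odds ratio
*observed* in the genotype-disease studies. Agreement supports a causal
role for the biomarker.

`mrpool` implements this pipeline end to end on summary data: genotype
counts in, verdicts out.

## Per-study effects

**Genotype contrasts.** A genotype table (ref/het/hom counts in cases and
controls) collapses to a 2×2 exposure-by-disease table under a genetic
model. The recessive model contrasts variant homozygotes against
reference homozygotes and *excludes* heterozygotes — the TT-vs-CC
contrast. The dominant model groups heterozygotes with the exposed class;
the allelic model counts alleles (two per homozygote, one of each per
heterozygote), doubling the totals.

**Odds ratios.** From a 2×2 table with cells $a,b,c,d$ the log odds ratio
is $\ln(ad/bc)$ with Woolf standard error $\sqrt{1/a+1/b+1/c+1/d}$. If
exactly one cell is zero the Haldane–Anscombe correction adds 0.5 to all
four cells (`zero_policy = "haldane"`, the default) so the study stays in
the pool without inventing information; a zero_policy of
`"not_estimable"` refuses instead. When a whole exposure row or disease
column is zero — a variant absent from every subject — no correction can
rescue the estimate and a `mrpool_not_estimable` condition is signalled
regardless of policy; the pipeline logs such studies and moves on. The
published software behind analyses of this kind does not state its sparse
table correction; Haldane–Anscombe is this package's documented choice.

**Continuous outcomes.** A biomarker contrast between two arms is the raw
mean difference with $SE = \sqrt{s_1^2/n_1 + s_2^2/n_2}$. Studies that
report only median, minimum and maximum are converted by the Hozo
estimators, whose formulas switch with sample size: mean
$(\min + 2\,\mathrm{med} + \max)/4$ for $n \le 25$, the median above
that; SD from the full range-based formula for $n \le 15$, range/4 for
$15 < n \le 70$, range/6 above. The cutoffs are the ones the original
derivation recommends; converted arms are tagged `hozo_estimated` so
provenance survives into reports.

## Pooling

Fixed-effect pooling is inverse-variance weighting,
$w_i = 1/se_i^2$. The random-effects model adds a between-study variance
$\tau^2$ estimated by the DerSimonian–Laird moment estimator:

$$Q = \sum w_i(\theta_i - \hat\theta_F)^2, \qquad
  \hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

after which $w_i^* = 1/(se_i^2 + \hat\tau^2)$ and the pooled estimate,
its SE and a z-based confidence interval follow from the starred
weights. Heterogeneity is summarized by
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100\%$ (defined as 0 when $Q = 0$)
and a chi-square upper-tail p-value at $k-1$ df, with significance
declared by a *strict* comparison against $\alpha = 0.05$.

Design choices worth stating:

* **DL only.** The moment estimator is the one the field's standard
  tools use for this analysis; REML and Paule–Mandel are deliberately
  not offered, so results are unambiguous.
* **z intervals, not t** (1.96 at 95%), matching the convention of the
  meta-analysis software this pipeline mirrors.
* **k = 1 is a degenerate pass-through**, returned unchanged with
  $Q = \tau^2 = I^2 = 0$ and a `degenerate` flag rather than an error:
  per-variant pipelines should report, not crash, on single-study
  variants — though they are never presented as pooled.
* Internals are full precision; rounding to the configured 2 decimals
  happens only in print methods and exported report tables.

## Publication bias

The classic Egger test regresses the standardized effect
$\theta_i/se_i$ on precision $1/se_i$ by unweighted OLS; under no
small-study effect the intercept is zero. The test statistic
$t = \hat\alpha / SE(\hat\alpha)$ uses a t distribution with $k-2$ df
(the original formulation), so at least three studies are required, and
a design with all SEs identical is rejected as degenerate. Funnel
coordinates are exported as (effect on the reporting scale, SE), the SE
axis conventionally inverted when plotted.

## MD → OR conversion

A pooled case-control mean difference on the biomarker is converted to
an odds ratio through the logistic-distribution identity used by
standard meta-analysis software: $d = \mathrm{MD}/s_\mathrm{pooled}$ and
$\ln \mathrm{OR} = d\,\pi/\sqrt{3}$. The identity is exactly linear in
MD on the log-OR scale and `or_to_md()` inverts it to machine precision.
No Hedges small-sample correction is applied by default because the
input is an already-pooled summary; `hedges_df` enables it when a
per-study conversion needs one. The standardizer defaults to the
df-weighted pooled SD across all arms of the case-control table.

## The expected-OR Mendelian randomization

Given a biomarker-disease odds ratio $\mathrm{OR}_\mathrm{bio}$ that
corresponds to a case-control biomarker difference $\mathrm{MD}$, and a
genotype effect $\Delta X$ on the same biomarker in healthy subjects,
log-linearity in the biomarker gives the expected genetic odds ratio

$$\mathrm{OR}_\mathrm{exp} =
  \exp\!\left(\ln(\mathrm{OR}_\mathrm{bio}) \cdot
  \frac{\Delta X}{\mathrm{MD}}\right).$$

With $\mathrm{OR}_\mathrm{bio} = 1.68$ per $\mathrm{MD} = 2.90$ µmol/L
and $\Delta X = 5.18$ µmol/L this evaluates to 2.526 — reported as 2.53
at two decimals; published analyses that round their intermediates print
2.52, which is why regression checks accept ±0.02 around printed values.

Its confidence interval follows the textbook log-OR construction:
$SE = \sqrt{\sum 1/f_i}$ over a list of counts, and
$\exp(\ln \mathrm{OR}_\mathrm{exp} \pm 1.96\,SE)$. The `frequencies`
list is an **explicit input**, not a hard-wired choice of totals: which
counts enter the reciprocal sum is an analyst decision that published
analyses do not always make recoverable, so the package refuses to guess.
The engine always reports the mathematically exact antilogs of its
log-scale limits.

The observed-vs-expected comparison uses two closed-interval primitives:
`ci_contained()` (is the observed CI entirely inside the expected CI?)
and `ci_overlap()` (do the two intervals intersect at all?). Boundary
touches count in both — a stated convention, since prose descriptions of
such checks rarely specify it. `run_mr()` composes the chain and, via
`run_biomarker_chain()`, each scalar can instead be produced by pooling
actual study tables: case-control MD → converted OR → pooled
$\Delta X$ → expected OR → verdicts.

One deliberate non-automation: outlier studies (e.g. a biomarker study
with a several-fold, non-normally-distributed case-control difference)
are excluded only through the explicit `exclude_studies` configuration
list, and every exclusion lands in the report's log with a reason code.
There is no defensible automatic rule for a decision of that kind.

## What the synthetic-data generator emulates

`sim_config()` fixes the study conditions; the `simulate_*` functions
are deterministic given its seed, with per-study substreams so that
extending `k` never perturbs earlier studies.

* **Genotype counts.** Controls follow Hardy–Weinberg proportions
  $(p^2, 2pq, q^2)$ at the risk-allele frequency. A study-specific
  log-OR $\theta_i \sim N(\mu, \tau^2)$ reweights the exposed genotype
  class(es) by $e^{\theta_i}$ (by $e^{2\theta_i}$ for variant
  homozygotes under the allelic model) and renormalizes, which makes the
  within-study odds ratio of the model's contrast *exactly*
  $e^{\theta_i}$; counts are multinomial at the sampled study sizes.
  This exposure-reweighting construction was chosen over individual-level
  logistic simulation because it hits the target OR exactly with no
  nuisance parameters.
* **Biomarker levels.** Normal within genotype, CC mean plus $\Delta X$
  for TT, common SD — the model every downstream formula
  (inverse-variance MD, Hozo, SMD conversion) assumes.

Defaults, chosen once as a realistic candidate-gene scenario: true OR
2.5 and $\tau = 0.2$ on the log scale, $k = 10$ studies of 100–500
subjects per arm, risk-allele frequency 0.30 (keeping both homozygote
classes populated at these sizes), and a homocysteine-like biomarker
(CC mean 10 µmol/L, SD 6 µmol/L, $\Delta X = 5.18$ µmol/L).

The generator does **not** emulate linkage disequilibrium, population
stratification, genotyping error, covariates or missingness — so
passing tests demonstrate the statistical machinery is correct under
the model's own assumptions, not that real cohorts are free of those
complications.

## Validation design and problem sizes

The test suite validates each stage against an independent route:
hand-computed fixtures (e.g. the three-study DL chain with $Q = 50$,
$\tau^2 = 0.96$); brute-force re-derivations of the DL and Egger
algebra on random instances (agreement to 1e-10); `metafor` as an
external cross-check; and Monte-Carlo recovery under the generator:

* 200 meta-analyses at $k = 15$, true OR 2.5, $\tau = 0.2$, with
  cohorts of 300–800 per arm at allele frequency 0.35 — larger than the
  generator's default studies so all four 2×2 cells stay big enough for
  the within-study normal approximation of the log-OR, which is what a
  parameter-recovery experiment is meant to isolate. The pooled log-OR
  mean must land within 3 Monte-Carlo SEs of $\ln 2.5$ and CI coverage
  in [0.90, 0.99] (z-based DL intervals run a little below nominal at
  moderate heterogeneity; that is a known property of the estimator,
  not a bug).
* Egger type-I error at $k = 10$ over 1000 null replicates, simulated at
  the effect-estimate level ($\theta_i \sim N(\theta, se_i^2)$ with SEs
  independent of effects) — the no-small-study-effect null under which
  the t-test is exact. Count-level simulation would instead probe the
  well-known spurious-asymmetry behaviour of log-OR funnel plots, a
  different question.
* Hozo mean recovery over 500 normal samples of $n = 50$.
* An end-to-end causal chain: true genetic log-OR equal to
  $\ln(1.68) \cdot 5/2.90$, $\tau = 0$ (the biomarker fully mediates a
  single common effect), 10 genotype-disease studies and 10
  genotype-biomarker studies of 500 per arm per replicate; the
  expected-OR CI draws its frequencies from the four aggregated 2×2
  cells. The observed pooled OR must fall inside the expected CI in at
  least 90% of 200 replicates.

These sizes keep the whole suite to a couple of minutes while leaving
the Monte-Carlo checks enough resolution to fail loudly if a formula is
wrong.

## Known limitations

* Only the DL estimator and z intervals; no Knapp–Hartung adjustment,
  meta-regression, subgroup or leave-one-out analysis.
* The Egger test is the classic unweighted form; no trim-and-fill or
  rank-correlation alternatives.
* The MR step is the literature-based scaling: no individual-level
  instrumental-variable estimation, no instrument-strength F statistics
  (the summary data this package consumes do not contain them), no
  pleiotropy-robust estimators.
* CI containment/overlap are descriptive verdicts, not formal tests of
  equality of effects.
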