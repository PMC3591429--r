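Package: mrpool
Title: Random-Effects Meta-Analysis and Literature-Based Mendelian
    Randomization for Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pooling case-control genetic association studies and
    continuous biomarker studies: per-study odds ratios from genotype counts
    under recessive, dominant or allelic contrasts with Haldane-Anscombe
    zero-cell handling; fixed-effect and DerSimonian-Laird random-effects
    inverse-variance pooling with Cochran's Q, tau-squared, I-squared and
    heterogeneity p-values; Egger regression and funnel-plot coordinates for
    publication-bias assessment; Hozo median/range to mean/SD estimation;
    standardized-mean-difference to odds-ratio conversion via the logistic
    identity; and a literature-based Mendelian randomization step that scales
    a biomarker-disease odds ratio by the genotype-biomarker effect to obtain
    an expected genetic odds ratio with a reciprocal-frequency confidence
    interval and observed-versus-expected containment and overlap verdicts.
    Includes a synthetic-data generator (Hardy-Weinberg genotype counts with
    between-study heterogeneity, genotype-stratified biomarker levels) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
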