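# Readers, writers, configuration and the two pipeline drivers that bind
# the modules together.

#' Analysis configuration
#'
#' @param model Genetic model for genotype contrasts (default recessive,
#'   the TT-vs-CC style contrast).
#' @param ci_level Confidence level for pooled estimates (default 0.95).
#' @param zero_policy Zero-cell policy for [or_from_table()].
#' @param het_alpha Significance level for the heterogeneity test.
#' @param rounding Decimal places used by report printing (default 2);
#'   machine-readable outputs always carry full precision.
#' @param exclude_studies Character vector of study_ids dropped before
#'   analysis, with the exclusion logged. Outlier removal is deliberate
#'   and explicit, never automatic.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(model = c("recessive", "dominant", "allelic"),
                            ci_level = 0.95,
                            zero_policy = c("haldane", "not_estimable"),
                            het_alpha = 0.05, rounding = 2,
                            exclude_studies = character(), seed = NULL) {
  model <- match.arg(model)
  zero_policy <- match.arg(zero_policy)
  stopifnot(ci_level > 0, ci_level < 1, het_alpha > 0, het_alpha < 1,
            rounding >= 0)
  structure(list(model = model, ci_level = ci_level,
                 zero_policy = zero_policy, het_alpha = het_alpha,
                 rounding = as.integer(rounding),
                 exclude_studies = as.character(exclude_studies),
                 seed = seed),
            class = "analysis_config")
}

#' Read a genotype-count study table
#'
#' Expected columns: `study_id, gene, variant, case_ref, case_het,
#' case_hom, control_ref, control_het, control_hom` (UTF-8, comma
#' delimiter, header row mandatory).
#'
#' @param path Path to the CSV file.
#' @return A list of [genotype_counts()] objects.
#' @export
read_genotype_studies <- function(path) {
  df <- read_checked_csv(path, c("study_id", "gene", "variant",
                                 "case_ref", "case_het", "case_hom",
                                 "control_ref", "control_het", "control_hom"))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      genotype_counts(row$study_id, row$gene, row$variant,
                      c(ref = row$case_ref, het = row$case_het,
                        hom = row$case_hom),
                      c(ref = row$control_ref, het = row$control_het,
                        hom = row$control_hom)),
      error = function(e) stop(sprintf("%s line %d: %s", path, i + 1,
                                       conditionMessage(e)), call. = FALSE))
  })
}

#' Write simulated genotype studies to the CSV schema
#'
#' @param studies List of [genotype_counts()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_genotype_studies <- function(studies, path) {
  rows <- lapply(studies, function(s) {
    data.frame(study_id = s$study_id, gene = s$gene, variant = s$variant,
               case_ref = s$case_counts[["ref"]],
               case_het = s$case_counts[["het"]],
               case_hom = s$case_counts[["hom"]],
               control_ref = s$control_counts[["ref"]],
               control_het = s$control_counts[["het"]],
               control_hom = s$control_counts[["hom"]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a continuous-arm study table
#'
#' Expected columns: `study_id, arm, n, mean, sd, median, min, max`. Per
#' row either `mean`+`sd` or `median`+`min`+`max` must be populated (the
#' other trio empty); median/range rows are converted to mean/SD with
#' [hozo_mean_sd()] and tagged `hozo_estimated`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `study_id`, `arm`, `n`, `mean`, `sd`,
#'   `provenance`.
#' @export
read_continuous_studies <- function(path) {
  df <- read_checked_csv(path, c("study_id", "arm", "n", "mean", "sd",
                                 "median", "min", "max"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    has_mean <- is.finite(row$mean) && is.finite(row$sd)
    has_median <- is.finite(row$median) && is.finite(row$min) && is.finite(row$max)
    if (has_mean == has_median)
      stop(sprintf("%s line %d: exactly one of mean/sd or median/min/max must be populated",
                   path, i + 1), call. = FALSE)
    arm <- tryCatch({
      if (has_mean) arm_summary(row$n, row$mean, row$sd)
      else arm_from_median_range(
        median_range_summary(row$n, row$median, row$min, row$max))
    }, error = function(e) stop(sprintf("%s line %d: %s", path, i + 1,
                                        conditionMessage(e)), call. = FALSE))
    data.frame(study_id = row$study_id, arm = row$arm, n = arm$n,
               mean = arm$mean, sd = arm$sd, provenance = arm$provenance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("%s: parse error: %s", path,
                                                  conditionMessage(e)),
                                          call. = FALSE))
  if (nrow(df) == 0)
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Per-study mean-difference estimates from a continuous-arm table
#'
#' @param arms Data frame as returned by [read_continuous_studies()].
#' @param arm1,arm2 Arm labels contrasted as `arm1 - arm2`
#'   (e.g. `"case"` vs `"control"`, or `"TT"` vs `"CC"`).
#' @return A list of [effect_estimate()] objects, one per study that has
#'   both arms.
#' @export
continuous_effects <- function(arms, arm1, arm2) {
  out <- list()
  for (sid in unique(arms$study_id)) {
    sub <- arms[arms$study_id == sid, ]
    r1 <- sub[sub$arm == arm1, ]
    r2 <- sub[sub$arm == arm2, ]
    if (nrow(r1) != 1 || nrow(r2) != 1) next
    out[[sid]] <- md_from_arms(
      arm_summary(r1$n, r1$mean, r1$sd, provenance = r1$provenance),
      arm_summary(r2$n, r2$mean, r2$sd, provenance = r2$provenance),
      study_id = sid)
  }
  out
}

#' Pooled within-group SD across all arms of a continuous table
#'
#' `sqrt(sum((n_i - 1) sd_i^2) / sum(n_i - 1))`, the usual variance-pooling
#' used as the standardizer for the MD-to-OR conversion.
#'
#' @param arms Data frame as returned by [read_continuous_studies()].
#' @return The pooled SD.
#' @export
pooled_sd_from_arms <- function(arms) {
  dfree <- arms$n - 1
  sqrt(sum(dfree * arms$sd^2) / sum(dfree))
}

#' Export forest-plot rows for a pooled analysis
#'
#' One row per study (estimate, CI, percent weight) plus a `summary` row,
#' all on the reporting scale (OR for log-OR input, MD otherwise).
#'
#' @param pooled A `pooled_result`.
#' @param estimates The list of [effect_estimate()] objects that was pooled.
#' @param path Optional CSV output path.
#' @return The forest data frame, invisibly if `path` is given.
#' @export
forest_table <- function(pooled, estimates, path = NULL) {
  stopifnot(inherits(pooled, "pooled_result"))
  th <- vapply(estimates, `[[`, numeric(1), "estimate")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  ids <- vapply(estimates, `[[`, character(1), "study_id")
  z <- stats::qnorm(1 - (1 - pooled$ci_level) / 2)
  rep_scale <- function(x) if (pooled$scale == "log_odds_ratio") exp(x) else x
  df <- data.frame(
    study_id = c(ids, "summary"),
    estimate = rep_scale(c(th, pooled$pooled_estimate)),
    ci_low = rep_scale(c(th - z * se, pooled$ci_low)),
    ci_high = rep_scale(c(th + z * se, pooled$ci_high)),
    weight_percent = c(100 * pooled$weights / sum(pooled$weights), NA),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export funnel-plot coordinates to CSV
#'
#' @param estimates List of [effect_estimate()] objects.
#' @param path Optional CSV output path.
#' @return The funnel data frame, invisibly if `path` is given.
#' @export
funnel_table <- function(estimates, path = NULL) {
  df <- funnel_coordinates(estimates)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Run the per-variant genetic meta-analysis pipeline
#'
#' For every gene/variant with at least two estimable studies: genotype
#' contrast under the configured model, per-study log odds ratios,
#' DerSimonian-Laird pooling, Egger regression when at least three studies
#' are available, and forest/funnel tables. Variants with fewer than two
#' estimable studies are listed as not pooled; every excluded or
#' non-estimable study appears in the exclusion log with a reason code.
#'
#' @param studies Path to a genotype-count CSV
#'   (see [read_genotype_studies()]) or a list of [genotype_counts()].
#' @param cfg An [analysis_config()].
#' @param out_dir Optional directory for `forest_<variant>.csv` and
#'   `funnel_<variant>.csv` exports.
#' @return An object of class `gene_meta_report`: per-variant results plus
#'   the exclusion log.
#' @export
run_gene_meta <- function(studies, cfg = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.character(studies)) studies <- read_genotype_studies(studies)
  log <- data.frame(study_id = character(), variant = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(study_id, variant, reason) {
    log[nrow(log) + 1, ] <<- list(study_id, variant, reason)
  }
  keys <- vapply(studies, function(s) paste(s$gene, s$variant, sep = "/"),
                 character(1))
  variants <- list()
  for (key in unique(keys)) {
    group <- studies[keys == key]
    ests <- list()
    for (s in group) {
      if (s$study_id %in% cfg$exclude_studies) {
        note(s$study_id, key, "excluded_by_config")
        next
      }
      est <- tryCatch(
        or_from_table(genotype_contrast(s, cfg$model),
                      zero_policy = cfg$zero_policy, study_id = s$study_id),
        mrpool_not_estimable = function(e) {
          note(s$study_id, key, "not_estimable")
          NULL
        })
      if (!is.null(est)) ests[[length(ests) + 1]] <- est
    }
    entry <- list(variant = key, k_estimable = length(ests), estimates = ests,
                  pooled = NULL, or = NULL, egger = NULL,
                  status = "not_pooled")
    if (length(ests) == 0) {
      entry$status <- "not_estimable"
    } else if (length(ests) >= 2) {
      entry$pooled <- pool_dl(ests, ci_level = cfg$ci_level)
      entry$or <- exponentiate_result(entry$pooled)
      entry$status <- "pooled"
      if (length(ests) >= 3)
        entry$egger <- tryCatch(egger_test(ests), error = function(e) NULL)
      if (!is.null(out_dir)) {
        slug <- gsub("[^A-Za-z0-9]+", "_", key)
        forest_table(entry$pooled, ests,
                     file.path(out_dir, paste0("forest_", slug, ".csv")))
        funnel_table(ests, file.path(out_dir, paste0("funnel_", slug, ".csv")))
      }
    } else {
      note(ests[[1]]$study_id, key, "fewer_than_two_studies")
    }
    variants[[key]] <- entry
  }
  structure(list(variants = variants, exclusions = log, config = cfg),
            class = "gene_meta_report")
}

#' @export
print.gene_meta_report <- function(x, ...) {
  dp <- x$config$rounding
  cat(sprintf("Genetic meta-analysis: %d variant(s)\n", length(x$variants)))
  for (v in x$variants) {
    if (v$status == "pooled") {
      cat(sprintf("  %s: OR %.*f (95%% CI %.*f-%.*f), k = %d, I^2 = %.0f%%, p_het = %s",
                  v$variant, dp, v$or$or, dp, v$or$or_ci_low, dp,
                  v$or$or_ci_high, v$pooled$k, v$pooled$i2_percent,
                  if (is.na(v$pooled$p_het)) "NA"
                  else format.pval(v$pooled$p_het, digits = 2)))
      if (!is.null(v$egger))
        cat(sprintf(", Egger p = %s", format.pval(v$egger$p_two_tailed, digits = 2)))
      cat("\n")
    } else {
      cat(sprintf("  %s: %s (k estimable = %d)\n", v$variant, v$status,
                  v$k_estimable))
    }
  }
  if (nrow(x$exclusions) > 0) {
    cat("Exclusions:\n")
    for (i in seq_len(nrow(x$exclusions)))
      cat(sprintf("  %s [%s]: %s\n", x$exclusions$study_id[i],
                  x$exclusions$variant[i], x$exclusions$reason[i]))
  }
  invisible(x)
}

#' Run the biomarker-to-expected-OR Mendelian randomization chain
#'
#' Reproduces the full biomarker pipeline: (1) pool the case-control
#' biomarker mean difference across studies (DerSimonian-Laird); (2)
#' convert it to an odds ratio through the logistic identity, standardized
#' by the pooled within-group SD; (3) pool the genotype biomarker
#' difference delta-X the same way; (4) scale the biomarker-disease OR by
#' `delta_x / md_case_control` on the log scale to obtain the expected
#' genetic OR with its reciprocal-frequency CI; (5) if an observed
#' genotype-disease pooled result is supplied, report containment and
#' overlap verdicts.
#'
#' Each pooling stage can be bypassed by supplying the corresponding
#' scalar in `mr` directly (`md_case_control` + `or_biomarker_disease`,
#' or `delta_x`), which is how a published worked example is reproduced.
#'
#' @param case_control Optional continuous-arm table (path or data frame,
#'   see [read_continuous_studies()]) with arms `"case"` and `"control"`.
#' @param genotype_biomarker Optional continuous-arm table with arms
#'   `"TT"` and `"CC"`.
#' @param mr Named list of scalar inputs: any of `or_biomarker_disease`,
#'   `md_case_control`, `delta_x`, `sd_pooled`, and (required)
#'   `frequencies`; optional `ci_z` (default 1.96).
#' @param observed Optional `pooled_result` on the log-OR scale.
#' @param cfg An [analysis_config()].
#' @return An object of class `biomarker_chain` collecting the stage
#'   results (`md_pool`, `conversion`, `dx_pool`, `mr_inputs`, `mr`).
#' @export
run_biomarker_chain <- function(case_control = NULL, genotype_biomarker = NULL,
                                mr = list(), observed = NULL,
                                cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(mr$frequencies))
    stop("`mr$frequencies` is required to build the expected-OR confidence interval",
         call. = FALSE)
  out <- list(md_pool = NULL, conversion = NULL, dx_pool = NULL)

  md_cc <- mr$md_case_control
  or_bio <- mr$or_biomarker_disease
  if (!is.null(case_control)) {
    if (is.character(case_control))
      case_control <- read_continuous_studies(case_control)
    case_control <- case_control[!case_control$study_id %in% cfg$exclude_studies, ]
    ests <- continuous_effects(case_control, "case", "control")
    if (length(ests) == 0) stop("no case/control study has both arms", call. = FALSE)
    out$md_pool <- pool_dl(ests, ci_level = cfg$ci_level)
    md_cc <- out$md_pool$pooled_estimate
    sd_pooled <- if (!is.null(mr$sd_pooled)) mr$sd_pooled
                 else pooled_sd_from_arms(case_control)
    out$conversion <- md_to_or(md_cc, sd_pooled, se_md = out$md_pool$se,
                               ci_level = cfg$ci_level)
    or_bio <- out$conversion$or
  }
  if (is.null(md_cc) || is.null(or_bio))
    stop("supply `case_control` data or both `mr$md_case_control` and `mr$or_biomarker_disease`",
         call. = FALSE)

  dx <- mr$delta_x
  if (!is.null(genotype_biomarker)) {
    if (is.character(genotype_biomarker))
      genotype_biomarker <- read_continuous_studies(genotype_biomarker)
    genotype_biomarker <-
      genotype_biomarker[!genotype_biomarker$study_id %in% cfg$exclude_studies, ]
    ests <- continuous_effects(genotype_biomarker, "TT", "CC")
    if (length(ests) == 0) stop("no genotype study has both TT and CC arms",
                                call. = FALSE)
    out$dx_pool <- pool_dl(ests, ci_level = cfg$ci_level)
    dx <- out$dx_pool$pooled_estimate
  }
  if (is.null(dx))
    stop("supply `genotype_biomarker` data or `mr$delta_x`", call. = FALSE)

  ci_z <- if (!is.null(mr$ci_z)) mr$ci_z else 1.96
  out$mr_inputs <- mr_inputs(or_bio, md_cc, dx, mr$frequencies, ci_z = ci_z)
  out$mr <- run_mr(out$mr_inputs, observed = observed)
  out$config <- cfg
  structure(out, class = "biomarker_chain")
}

#' @export
print.biomarker_chain <- function(x, ...) {
  dp <- x$config$rounding
  cat("Biomarker-to-expected-OR chain\n")
  if (!is.null(x$md_pool))
    cat(sprintf("  pooled case-control MD %.*f (95%% CI %.*f-%.*f), k = %d\n",
                dp, x$md_pool$pooled_estimate, dp, x$md_pool$ci_low,
                dp, x$md_pool$ci_high, x$md_pool$k))
  if (!is.null(x$conversion))
    cat(sprintf("  converted biomarker-disease OR %.*f (95%% CI %.*f-%.*f)\n",
                dp, x$conversion$or, dp, x$conversion$or_ci_low,
                dp, x$conversion$or_ci_high))
  if (!is.null(x$dx_pool))
    cat(sprintf("  pooled genotype delta-X %.*f (95%% CI %.*f-%.*f), k = %d\n",
                dp, x$dx_pool$pooled_estimate, dp, x$dx_pool$ci_low,
                dp, x$dx_pool$ci_high, x$dx_pool$k))
  print(x$mr, digits = dp)
  invisible(x)
}
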