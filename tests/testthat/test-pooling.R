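test_that("fixed-effect pooling is inverse-variance weighting", {
  one <- pool_fixed(list(effect_estimate(0.5, 0.2)))
  expect_equal(one$pooled_estimate, 0.5)
  expect_equal(one$se, 0.2)
  expect_true(one$degenerate)

  two <- pool_fixed(list(effect_estimate(1, 1), effect_estimate(0, 1)))
  expect_equal(two$pooled_estimate, 0.5)
  expect_equal(two$se, 1 / sqrt(2))

  # hand inverse-variance arithmetic: weights 100, 25, 11.111...
  three <- pool_fixed(list(effect_estimate(0.2, 0.1),
                           effect_estimate(0.4, 0.2),
                           effect_estimate(0.6, 0.3)))
  expect_equal(three$pooled_estimate, (20 + 10 + 6 + 2 / 3) / (136 + 1 / 9))
  expect_equal(three$pooled_estimate, 0.26938776, tolerance = 1e-6)
  expect_equal(three$se, 1 / sqrt(136 + 1 / 9))
  expect_equal(three$se, 0.0857, tolerance = 1e-3)

  expect_error(pool_fixed(list(
    effect_estimate(1, 1, "log_odds_ratio"),
    effect_estimate(1, 1, "mean_difference"))), "scales")
  expect_error(pool_fixed(list()), "no estimates")
})

test_that("DerSimonian-Laird matches the hand-computed three-study fixture", {
  ests <- list(effect_estimate(0, 0.2, study_id = "a"),
               effect_estimate(1, 0.2, study_id = "b"),
               effect_estimate(2, 0.2, study_id = "c"))
  r <- pool_dl(ests)
  expect_equal(r$q, 50)
  expect_equal(r$tau2, 0.96)
  expect_equal(unname(r$weights), rep(1, 3))
  expect_equal(r$pooled_estimate, 1)
  expect_equal(r$se, 1 / sqrt(3))
  expect_equal(r$i2_percent, (50 - 2) / 50 * 100)
  expect_equal(r$p_het, pchisq(50, 2, lower.tail = FALSE))
})

test_that("DL degenerates gracefully: homogeneity and single studies", {
  same <- pool_dl(list(effect_estimate(0.5, 0.2), effect_estimate(0.5, 0.2)))
  expect_equal(same$q, 0)
  expect_equal(same$tau2, 0)
  expect_equal(same$i2_percent, 0)
  expect_equal(same$pooled_estimate, 0.5)
  expect_equal(same$se, 0.2 / sqrt(2))

  # tau2 = 0 reduces DL to the fixed-effect answer
  set.seed(41)
  ests <- lapply(1:4, function(i) effect_estimate(0.3, runif(1, 0.1, 0.5)))
  dl <- pool_dl(ests); fx <- pool_fixed(ests)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$pooled_estimate, fx$pooled_estimate)
  expect_equal(dl$se, fx$se)

  k1 <- pool_dl(list(effect_estimate(0.7, 0.3, study_id = "only")))
  expect_true(k1$degenerate)
  expect_equal(k1$pooled_estimate, 0.7)
  expect_equal(k1$se, 0.3)
  expect_equal(k1$q, 0)
  expect_equal(k1$tau2, 0)
  expect_true(is.na(k1$p_het))
})

test_that("DL agrees with the brute-force oracle and with metafor", {
  skip_if_not_installed("metafor")
  set.seed(101)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    ests <- rand_estimates(k)
    th <- est_vec(ests, "estimate"); se <- est_vec(ests, "se")
    r <- pool_dl(ests)
    o <- dl_oracle(th, se)
    expect_equal(r$pooled_estimate, o$pooled, tolerance = 1e-12)
    expect_equal(r$se, o$se, tolerance = 1e-12)
    expect_equal(r$tau2, o$tau2, tolerance = 1e-12)
    expect_equal(r$q, o$q, tolerance = 1e-12)

    m <- metafor::rma(yi = th, sei = se, method = "DL")
    expect_equal(r$pooled_estimate, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(r$se, m$se, tolerance = 1e-8)
    expect_equal(r$tau2, m$tau2, tolerance = 1e-8)
    expect_equal(r$q, m$QE, tolerance = 1e-8)
    expect_equal(r$p_het, m$QEp, tolerance = 1e-8)
  }
})

test_that("pooled estimates respect convexity and weight monotonicity", {
  set.seed(51)
  for (i in 1:20) {
    ests <- rand_estimates(sample(2:8, 1))
    th <- est_vec(ests, "estimate")
    for (r in list(pool_fixed(ests), pool_dl(ests))) {
      expect_gte(r$pooled_estimate, min(th) - 1e-12)
      expect_lte(r$pooled_estimate, max(th) + 1e-12)
      expect_true(r$ci_low <= r$pooled_estimate && r$pooled_estimate <= r$ci_high)
      expect_gte(r$tau2, 0)
      expect_true(r$i2_percent >= 0 && r$i2_percent <= 100)
    }
    # inflate one study's SE: its fixed-effect weight strictly decreases
    j <- sample(seq_along(ests), 1)
    inflated <- ests
    inflated[[j]] <- effect_estimate(ests[[j]]$estimate, ests[[j]]$se * 2,
                                     study_id = ests[[j]]$study_id)
    expect_lt(pool_fixed(inflated)$weights[j], pool_fixed(ests)$weights[j])
  }

  # under random effects the same holds at fixed tau2; with homogeneous
  # estimates tau2 stays 0 before and after, making the comparison clean
  hom <- lapply(c(0.1, 0.2, 0.3), function(s) effect_estimate(0.4, s))
  hom_inf <- hom
  hom_inf[[2]] <- effect_estimate(0.4, 0.4)
  expect_equal(pool_dl(hom)$tau2, 0)
  expect_equal(pool_dl(hom_inf)$tau2, 0)
  expect_lt(pool_dl(hom_inf)$weights[2], pool_dl(hom)$weights[2])
})

test_that("pooled log-OR results exponentiate componentwise", {
  ests <- list(effect_estimate(log(2.5), 0.3), effect_estimate(log(2.5), 0.3))
  r <- pool_dl(ests)
  e <- exponentiate_result(r)
  expect_equal(e$or, 2.5)
  expect_equal(e$or_ci_low, exp(r$ci_low))
  expect_equal(e$or_ci_high, exp(r$ci_high))

  md <- pool_dl(list(effect_estimate(1, 1, "mean_difference"),
                     effect_estimate(2, 1, "mean_difference")))
  expect_error(exponentiate_result(md), "log-odds-ratio")
})

test_that("heterogeneity verdict uses a strict threshold", {
  mk <- function(p) {
    r <- pool_dl(list(effect_estimate(0, 1), effect_estimate(0, 1)))
    r$p_het <- p
    r
  }
  expect_true(heterogeneity_significant(mk(0.002)))
  expect_false(heterogeneity_significant(mk(0.33)))
  expect_false(heterogeneity_significant(mk(0.05)))  # boundary: not significant
  expect_true(heterogeneity_significant(mk(0.06), alpha = 0.1))
  k1 <- pool_dl(list(effect_estimate(0.7, 0.3)))
  expect_true(is.na(heterogeneity_significant(k1)))
})
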