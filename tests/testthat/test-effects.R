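test_that("genotype contrasts select the right cells under each model", {
  gc <- genotype_counts("s1", "MTHFR", "C677T",
                        c(ref = 50, het = 30, hom = 20),
                        c(ref = 60, het = 30, hom = 10))

  rec <- genotype_contrast(gc, "recessive")
  expect_equal(unlist(rec[1:4], use.names = FALSE), c(20, 50, 10, 60))

  dom <- genotype_contrast(gc, "dominant")
  expect_equal(unlist(dom[1:4], use.names = FALSE), c(50, 50, 40, 60))

  all <- genotype_contrast(gc, "allelic")
  expect_equal(all$exposed_cases, 2 * 20 + 30)
  expect_equal(all$unexposed_cases, 2 * 50 + 30)
  expect_equal(all$exposed_controls, 2 * 10 + 30)
  expect_equal(all$unexposed_controls, 2 * 60 + 30)

  # no variant carriers: exposed cells empty but table still valid
  mono <- genotype_contrast(
    genotype_counts("s2", "F2", "G20210A", c(ref = 100, het = 0, hom = 0),
                    c(ref = 100, het = 0, hom = 0)), "recessive")
  expect_equal(unlist(mono[1:4], use.names = FALSE), c(0, 100, 0, 100))

  expect_error(genotype_contrast(gc, "additive"))
})

test_that("genotype contrasts conserve counts", {
  set.seed(11)
  for (i in 1:25) {
    ca <- c(ref = rpois(1, 40), het = rpois(1, 30), hom = rpois(1, 10) + 1)
    co <- c(ref = rpois(1, 50), het = rpois(1, 25), hom = rpois(1, 8) + 1)
    gc <- genotype_counts("x", "G", "v", ca, co)
    rec <- genotype_contrast(gc, "recessive")
    expect_lte(rec$exposed_cases + rec$unexposed_cases, sum(ca))
    all <- genotype_contrast(gc, "allelic")
    expect_equal(all$exposed_cases + all$unexposed_cases, 2 * sum(ca))
    expect_equal(all$exposed_controls + all$unexposed_controls, 2 * sum(co))
  }
})

test_that("log odds ratio and SE follow the Woolf formulas", {
  balanced <- or_from_table(two_by_two(10, 10, 10, 10))
  expect_equal(balanced$estimate, 0)
  expect_equal(balanced$se, sqrt(0.4))
  expect_equal(balanced$scale, "log_odds_ratio")

  est <- or_from_table(two_by_two(10, 90, 5, 95))
  expect_equal(exp(est$estimate), (10 * 95) / (90 * 5))
  expect_equal(est$estimate, log(2.111111), tolerance = 1e-6)
  expect_equal(est$se, sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95))
})

test_that("swapping case and control arms negates the log-OR, SE unchanged", {
  set.seed(21)
  for (i in 1:25) {
    cells <- rpois(4, 30) + 1
    a <- or_from_table(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    b <- or_from_table(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(a$estimate, -b$estimate)
    expect_equal(a$se, b$se)
  }
})

test_that("zero cells trigger Haldane correction or a not-estimable signal", {
  # single zero cell, haldane: all four cells get +0.5
  est <- or_from_table(two_by_two(0, 100, 10, 90), zero_policy = "haldane")
  expect_equal(est$estimate, log((0.5 * 90.5) / (100.5 * 10.5)))
  expect_equal(est$se, sqrt(1 / 0.5 + 1 / 100.5 + 1 / 10.5 + 1 / 90.5))

  expect_error(or_from_table(two_by_two(0, 100, 10, 90),
                             zero_policy = "not_estimable"),
               class = "mrpool_not_estimable")

  # whole exposure row zero: not estimable under any policy
  expect_error(or_from_table(two_by_two(0, 100, 0, 100), "haldane"),
               class = "mrpool_not_estimable")
  expect_error(or_from_table(two_by_two(0, 100, 0, 100), "not_estimable"),
               class = "mrpool_not_estimable")
  # whole disease column zero
  expect_error(or_from_table(two_by_two(0, 0, 10, 90), "haldane"),
               class = "mrpool_not_estimable")

  # with all cells >= 1 the two policies agree
  set.seed(31)
  for (i in 1:10) {
    cells <- rpois(4, 20) + 1
    h <- or_from_table(two_by_two(cells[1], cells[2], cells[3], cells[4]), "haldane")
    n <- or_from_table(two_by_two(cells[1], cells[2], cells[3], cells[4]), "not_estimable")
    expect_identical(h$estimate, n$estimate)
    expect_identical(h$se, n$se)
  }
})

test_that("mean differences carry the two-sample standard error", {
  md <- md_from_arms(arm_summary(50, 15, 4), arm_summary(50, 10, 4))
  expect_equal(md$estimate, 5)
  expect_equal(md$se, sqrt(16 / 50 + 16 / 50))
  expect_equal(md$scale, "mean_difference")

  self <- md_from_arms(arm_summary(30, 12, 3), arm_summary(30, 12, 3))
  expect_equal(self$estimate, 0)

  uneq <- md_from_arms(arm_summary(4, 12, 3), arm_summary(9, 10, 3))
  expect_equal(uneq$se, sqrt(9 / 4 + 9 / 9))

  expect_error(md_from_arms(arm_summary(10, 5, 0, "hozo_estimated"),
                            arm_summary(10, 4, 0, "hozo_estimated")),
               "degenerate")
})

test_that("Hozo mean/SD estimates follow the sample-size regimes", {
  # degenerate range
  deg <- hozo_mean_sd(median_range_summary(10, 5, 5, 5))
  expect_equal(deg$mean, 5)
  expect_equal(deg$sd, 0)

  # n <= 15: full formula for SD, weighted mean formula
  small <- hozo_mean_sd(median_range_summary(12, 4, 1, 9))
  expect_equal(small$mean, (1 + 2 * 4 + 9) / 4)
  expect_equal(small$sd, sqrt(((1 - 2 * 4 + 9)^2 / 4 + (9 - 1)^2) / 12))

  # 15 < n <= 70: range/4 and (n <= 25) weighted mean
  mid <- hozo_mean_sd(median_range_summary(50, 3, 1, 5))
  expect_equal(mid$mean, 3)  # n > 25: median
  expect_equal(mid$sd, 1)
  mid25 <- hozo_mean_sd(median_range_summary(20, 3, 1, 5))
  expect_equal(mid25$mean, (1 + 2 * 3 + 5) / 4)

  # n > 70: range/6
  big <- hozo_mean_sd(median_range_summary(100, 12, 6, 24))
  expect_equal(big$mean, 12)
  expect_equal(big$sd, 3)

  expect_error(median_range_summary(10, 5, 6, 4), "min")
})

test_that("Hozo conversion produces a tagged arm summary", {
  arm <- arm_from_median_range(median_range_summary(50, 3, 1, 5))
  expect_s3_class(arm, "arm_summary")
  expect_equal(arm$provenance, "hozo_estimated")
  expect_equal(arm$mean, 3)
  expect_equal(arm$sd, 1)
})

test_that("constructors validate their invariants", {
  expect_error(genotype_counts("s", "G", "v", c(ref = 0, het = 0, hom = 0),
                               c(ref = 1, het = 0, hom = 0)), "non-zero")
  expect_error(genotype_counts("s", "G", "v", c(ref = -1, het = 2, hom = 0),
                               c(ref = 1, het = 0, hom = 0)), "non-negative")
  expect_error(effect_estimate(0.5, -0.1), "positive")
  expect_error(effect_estimate(0.5, 0), "positive")
  expect_error(two_by_two(-1, 2, 3, 4))
  expect_error(arm_summary(1, 10, 2), "n >= 2")
  expect_error(median_range_summary(10, 7, 1, 5), "median")
})
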