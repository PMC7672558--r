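test_that("reciprocal-logit matches hand evaluation and is strictly decreasing", {
  expect_equal(reciprocal_logit(50), log(0.02 / 0.98), tolerance = 1e-12)
  expect_equal(reciprocal_logit(50), -3.8918, tolerance = 1e-4)
  expect_equal(reciprocal_logit(2), 0)
  y <- seq(1.01, 300, length.out = 200)
  expect_true(all(diff(reciprocal_logit(y)) < 0))
  expect_error(reciprocal_logit(1), "percent")
  expect_error(reciprocal_logit(c(50, 0.5)), "percent")
})

test_that("D'Agostino-Pearson omnibus matches a reference implementation", {
  # frozen reference values from scipy.stats.normaltest
  x <- c(2.3, 1.1, 4.5, 0.2, 3.3, 2.2, 5.1, 0.9, 2.8, 1.7, 3.9, 2.5)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 0.27270566311393835, tolerance = 1e-10)
  expect_equal(r$p, 0.8725347203874566, tolerance = 1e-10)
  y <- c(1.0, 1.2, 0.8, 5.0, 0.9, 1.1, 1.3, 0.7, 1.05, 0.95)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 27.107206166455548, tolerance = 1e-10)
  expect_equal(r2$p, 1.2994063089560213e-06, tolerance = 1e-8)
  z <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.3, 1.5, 1.8, 2.2, 2.7, 3.3,
         4.1, 5.2, 6.6, 8.4, 10.7, 13.7, 17.5)
  r3 <- dagostino_pearson(z)
  expect_equal(r3$statistic, 11.573752062728865, tolerance = 1e-10)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
  expect_error(dagostino_pearson(rep(1, 10)), "constant")
})

test_that("gate decides parametric for Normal and nonparametric for lognormal data", {
  set.seed(51)
  n_rep <- 200
  para_all <- para_maj <- nonpara <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(50); b <- rnorm(50)
    if (normality_gate(a, b)$decision == "parametric")
      para_all <- para_all + 1L
    if (normality_gate(a, b, rule = "majority")$decision == "parametric")
      para_maj <- para_maj + 1L
    al <- exp(rnorm(50, 0, 1.2)); bl <- exp(rnorm(50, 0, 1.2))
    if (normality_gate(al, bl)$decision == "nonparametric")
      nonpara <- nonpara + 1L
  }
  # the conservative all-tests-must-pass rule trips on any of 6 tests,
  # so its Normal-data parametric rate is bounded below by 0.95^6 (the
  # independent-test floor; positive dependence raises it)
  expect_gte(para_all / n_rep, 0.95^6)
  expect_gte(para_maj / n_rep, 0.95)
  expect_gte(nonpara / n_rep, 0.95)
})

test_that("gate records inapplicable tests instead of failing, and degenerates to nonparametric", {
  # n = 6: D'Agostino-Pearson (needs n >= 8) must be not-applicable
  g <- normality_gate(c(1.2, 2.1, 2.9, 4.2, 5.1, 6.3),
                      c(2.2, 3.1, 3.9, 5.2, 6.1, 7.3))
  dago <- g$report[g$report$test == "dagostino_pearson", ]
  expect_true(all(!dago$applicable))
  others <- g$report[g$report$test != "dagostino_pearson", ]
  expect_true(all(others$applicable))
  # constant sample: all tests inapplicable there; gate falls through
  g2 <- normality_gate(rep(5, 10), rnorm(10))
  expect_true(all(!g2$report$applicable[g2$report$group == "a"]))
  g3 <- normality_gate(rep(5, 10), rep(7, 10))
  expect_identical(g3$decision, "nonparametric")
  expect_error(normality_gate(c(1, 2), rnorm(10)), "3 observations")
})

test_that("forced t comparison equals the closed-form Welch oracle", {
  n_vals <- c(1, 2, 3, 4, 5); h_vals <- c(2, 3, 4, 5, 6)
  cmp <- compare_groups(n_vals, h_vals, force_test = "t")
  # hand-computed Welch statistic: means 3 and 4, variances 2.5 each
  se <- sqrt(2.5 / 5 + 2.5 / 5)
  expect_equal(cmp$statistic, (4 - 3) / se, tolerance = 1e-12)
  df <- (2.5 / 5 + 2.5 / 5)^2 / ((2.5 / 5)^2 / 4 + (2.5 / 5)^2 / 4)
  expect_equal(cmp$p, 2 * pt(-1, df), tolerance = 1e-12)
  expect_equal(cmp$percent_change, 100 * (4 - 3) / 3, tolerance = 1e-12)
})

test_that("identical groups give zero percent change and a large p", {
  x <- c(10, 12, 14, 16, 18, 20, 11, 13, 15, 17)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$percent_change, 0)
  expect_gt(cmp$p, 0.05)
})

test_that("swapping group labels flips the t statistic and preserves p", {
  set.seed(52)
  for (i in 1:20) {
    a <- rnorm(12, 10, 2); b <- rnorm(12, 11, 2)
    f <- compare_groups(a, b, force_test = "t")
    r <- compare_groups(b, a, force_test = "t")
    expect_equal(f$statistic, -r$statistic, tolerance = 1e-12)
    expect_equal(f$p, r$p, tolerance = 1e-12)
    fw <- compare_groups(a, b, force_test = "wilcoxon")
    rw <- compare_groups(b, a, force_test = "wilcoxon")
    expect_equal(fw$p, rw$p, tolerance = 1e-12)
  }
})

test_that("transform flag is honoured and does not change the raw-scale summary", {
  set.seed(53)
  a <- runif(10, 60, 95); b <- runif(10, 40, 80)
  cmp <- compare_groups(a, b, transform = TRUE, force_test = "t")
  expect_identical(cmp$transform, "reciprocal_logit")
  expect_equal(cmp$mean[["normoxia"]], mean(a))
  expect_equal(cmp$percent_change, 100 * (mean(b) - mean(a)) / mean(a))
  # the statistic is computed on the transformed scale
  raw <- compare_groups(a, b, transform = FALSE, force_test = "t")
  expect_false(isTRUE(all.equal(cmp$statistic, raw$statistic)))
})

test_that("paired design selects paired tests and enforces equal n", {
  set.seed(54)
  a <- rnorm(10, 10); b <- a + rnorm(10, 1, 0.3)
  cmp <- compare_groups(a, b, design = "paired")
  expect_true(cmp$test_used %in% c("paired_t", "wilcoxon_paired"))
  expect_error(compare_groups(a, b[1:5], design = "paired"), "equal")
})

test_that("percent change handles the documented summaries and zero mean", {
  expect_equal(percent_change(rep(100, 3), rep(20, 3)), -80)
  expect_equal(percent_change(rep(100, 3), rep(138, 3)), 38)
  expect_equal(percent_change(c(5, 15), c(10, 10)), 0)
  expect_error(percent_change(c(-1, 1), c(2, 2)), "zero")
})

test_that("simulated hypoxia contrast recovers the expected MR direction", {
  for (seed in 1:10) {
    sim <- simulate_flux_plates(flux_sim_config(seed = seed))
    prof <- flux_pipeline(list(sim$normoxia, sim$hypoxia))
    pc <- percent_change(prof$MR[prof$condition == "normoxia"],
                         prof$MR[prof$condition == "hypoxia"])
    expect_lt(pc, 0)
  }
})

test_that("compare_profiles transforms exactly the percentage metrics", {
  sim <- simulate_flux_plates(flux_sim_config(seed = 55))
  cmp <- compare_profiles(flux_pipeline(list(sim$normoxia, sim$hypoxia)))
  expect_setequal(cmp$metric[cmp$transform == "reciprocal_logit"],
                  c("CR_pct_MR", "PL_pct_MR", "SRC_pct_MR"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})
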