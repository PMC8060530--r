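test_that("reconstructed period tables reproduce the published statistics", {
  prev_pre <- c(43.0, 17.8, 26.7, 11.8)
  prev_lock <- c(52.8, 10.3, 34.6, 2.3)
  res <- contrast_from_prevalences(960, 214, prev_pre, prev_lock)
  expect_equal(res$n_in_pre, c(413L, 171L, 256L, 113L))
  expect_equal(res$n_in_lockdown, c(113L, 22L, 74L, 5L))
  expect_equal(round(res$chi2, 2), c(6.38, 6.69, 5.04, 16.20))
  expect_equal(round(res$p_value[1:3], 3), c(0.012, 0.010, 0.025))
  expect_lt(res$p_value[4], 0.001)
})

test_that("the continuity-corrected statistic matches the standard test", {
  # independent oracle: stats::chisq.test with Yates correction
  tabs <- list(matrix(c(413, 547, 113, 101), 2, 2, byrow = TRUE),
               matrix(c(171, 789, 22, 192), 2, 2, byrow = TRUE),
               matrix(c(256, 704, 74, 140), 2, 2, byrow = TRUE),
               matrix(c(113, 847, 5, 209), 2, 2, byrow = TRUE))
  for (tb in tabs) {
    ref <- suppressWarnings(stats::chisq.test(tb, correct = TRUE))
    got <- yates_chi_square(tb)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  set.seed(17)
  for (r in 1:200) {
    tb <- matrix(rpois(4, 40) + 1, 2, 2)
    ref <- suppressWarnings(stats::chisq.test(tb, correct = TRUE))
    expect_equal(yates_chi_square(tb)$chi2, unname(ref$statistic),
                 tolerance = 1e-10)
  }
})

test_that("the correction is floored and bounded by the Pearson statistic", {
  # proportionally identical table: zero after the correction floor
  even <- matrix(50, 2, 2)
  expect_equal(yates_chi_square(even)$chi2, 0)
  expect_equal(yates_chi_square(even)$p_value, 1)
  # swapping rows together with relabelling leaves the statistic unchanged
  tb <- matrix(c(413, 547, 113, 101), 2, 2, byrow = TRUE)
  expect_equal(yates_chi_square(tb[2:1, ])$chi2, yates_chi_square(tb)$chi2)
  set.seed(23)
  for (r in 1:1000) {
    tb <- matrix(rpois(4, rgamma(4, 2, 0.05)) + 1, 2, 2)
    expect_lte(yates_chi_square(tb)$chi2, pearson_chi_square(tb) + 1e-12)
  }
  expect_error(yates_chi_square(matrix(c(0, 0, 5, 5), 2, 2)), "degenerate")
  expect_error(contingency_table(c(1, 1, 2), rep("pre_lockdown", 3), 1),
               "degenerate margin")
})

test_that("percent change is the signed relative prevalence difference", {
  expect_equal(round(percent_change(43.0, 52.8), 1), 22.8)
  expect_equal(round(percent_change(26.7, 34.6), 1), 29.6)
  expect_equal(round(percent_change(17.8, 10.3), 1), -42.1)
  expect_equal(percent_change(12.3, 12.3), 0)
  expect_error(percent_change(0, 5), "zero baseline")
  expect_equal(format_percent_change(percent_change(17.8, 10.3)),
               "42.1% decrease")
  expect_equal(format_percent_change(percent_change(43.0, 52.8)),
               "22.8% increase")
})

test_that("exact binomial interval matches tail-inversion oracles", {
  ci <- clopper_pearson_ci(7, 960)
  expect_equal(round(unname(ci), 1), c(0.3, 1.5))
  # brackets the point estimate
  expect_lt(ci[["lower"]], 100 * 7 / 960)
  expect_gt(ci[["upper"]], 100 * 7 / 960)

  # oracle 1: stats::binom.test
  bt <- stats::binom.test(7, 960)$conf.int * 100
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)

  # oracle 2: direct root-finding on the binomial tails
  lower_root <- uniroot(function(p) pbinom(6, 960, p) - 0.975,
                        c(1e-8, 0.5), tol = 1e-12)$root
  upper_root <- uniroot(function(p) pbinom(7, 960, p) - 0.025,
                        c(1e-8, 0.5), tol = 1e-12)$root
  expect_equal(ci[["lower"]], 100 * lower_root, tolerance = 1e-6)
  expect_equal(ci[["upper"]], 100 * upper_root, tolerance = 1e-6)

  expect_equal(clopper_pearson_ci(0, 100)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(100, 100)[["upper"]], 100)
  expect_error(clopper_pearson_ci(8, 7), "0..n")
})

test_that("the exact interval attains nominal coverage for rare events", {
  set.seed(29)
  x <- rbinom(10000, 960, 0.007)
  cis <- t(vapply(x, function(xi) clopper_pearson_ci(xi, 960), numeric(2)))
  covered <- cis[, 1] <= 0.7 & cis[, 2] >= 0.7
  expect_gte(mean(covered), 0.945)
})

test_that("contingency tables and reports are consistent with their margins", {
  labels <- c(rep(1, 60), rep(2, 30), rep(3, 10))
  periods <- rep(c("pre_lockdown", "lockdown"), 50)
  tab <- contingency_table(labels, periods, 1)
  expect_equal(sum(tab), 100)
  expect_equal(unname(rowSums(tab)), c(50, 50))
  expect_error(contingency_table(labels, periods, 99), "unknown profile")

  asg <- structure(list(labels = labels, patterns = NULL,
                        prevalence = prop.table(table(labels)),
                        n_rows = 100, method = "truth"),
                   class = "profile_assignment")
  rep_out <- build_report(asg, periods, top_m = 2)
  expect_equal(nrow(rep_out), 3)  # 2 profiles + pooled rare row
  expect_equal(rep_out$profile[3], "rare")
  expect_false(is.na(rep_out$ci_lower_pct[3]))
  # per-period prevalences sum to 100
  expect_equal(sum(rep_out$prev_pre_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep_out$prev_lock_pct), 100, tolerance = 1e-9)
  expect_error(build_report(asg, rep("pre_lockdown", 100)), "both periods")
})
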