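test_that("pattern profiles are counted, ordered and labelled correctly", {
  Z <- matrix(c(0, 0, 1, 0,
                0, 0, 0, 1), nrow = 4)
  st <- ibp_state(Z, matrix(0, 2, 3))
  asg <- assign_profiles(st, method = "sampled_pattern")
  expect_length(asg$prevalence, 3)
  expect_equal(unname(asg$prevalence), c(0.5, 0.25, 0.25))
  # the most prevalent profile is the all-zero pattern
  expect_equal(unname(asg$patterns[1, ]), c(0, 0))
  # labels conserve rows
  expect_equal(sum(table(asg$labels)), 4)
  expect_equal(asg$labels[1], asg$labels[2])

  # single profile when all rows identical
  Z1 <- matrix(1, 5, 1)
  asg1 <- assign_profiles(ibp_state(Z1, matrix(0, 1, 3)),
                          method = "sampled_pattern")
  expect_equal(unname(asg1$prevalence), 1)
  expect_equal(coverage(asg1, 1), 1)

  # K features allow at most 2^K patterns
  set.seed(44)
  Z3 <- matrix(rbinom(300, 1, 0.5), 100, 3)
  Z3[, colSums(Z3) == 0] <- 1
  asg3 <- assign_profiles(ibp_state(Z3, matrix(0, 3, 2)),
                          method = "sampled_pattern")
  expect_lte(length(asg3$prevalence), 8)
  expect_true(all(diff(asg3$prevalence) <= 0))
  expect_equal(sum(asg3$prevalence), 1, tolerance = 1e-9)
})

test_that("posterior-mode assignment uses prior and masked likelihood", {
  # two features with clearly separated weights; row 4's observations pin
  # it to feature 1 even though its sampled row says otherwise
  Z <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), nrow = 4)
  A <- rbind(c(0.6, 0, 0), c(0, 0.6, 0))
  st <- ibp_state(Z, A, sigma_x = 0.1)
  vals <- rbind(c(0.6, 0.0, NA),
                c(0.6, NA, 0),
                c(NA, 0.6, 0),
                c(0.6, 0.0, NA))  # row 4 looks like feature 1
  obs <- list(values = vals, mask = !is.na(vals))
  asg <- assign_profiles(st, obs, method = "map_pattern")
  expect_equal(asg$labels[4], asg$labels[1])
  # an uninformative row falls back to the prior-preferred pattern
  vals2 <- vals; vals2[4, ] <- NA; vals2[4, 3] <- 0
  asg2 <- assign_profiles(st, list(values = vals2, mask = !is.na(vals2)),
                          method = "map_pattern")
  # both features have m/N = 0.5; the likelihood at the third item is
  # identical for all patterns, so ties resolve deterministically
  expect_identical(asg2$labels,
                   assign_profiles(st, list(values = vals2,
                                            mask = !is.na(vals2)),
                                   method = "map_pattern")$labels)
  expect_error(assign_profiles(st, method = "map_pattern"), "observation")
})

test_that("signatures are masked empirical positive rates", {
  labels_Z <- matrix(c(0, 0, 1, 1), 4, 1)
  st <- ibp_state(labels_Z, matrix(0, 1, 3))
  vals <- rbind(c(0.9, 0.2, NA),
                c(0.8, NA, NA),
                c(0.1, 0.6, NA),
                c(0.2, 0.7, NA))
  obs <- list(values = vals, mask = !is.na(vals))
  asg <- assign_profiles(st, method = "sampled_pattern")
  sig <- unname(feature_signature(asg, obs))
  # profile 1 = rows 1,2 (pattern 0): all positive at item 1
  expect_equal(sig[1, 1], 1)
  expect_equal(sig[1, 2], 0)   # one observed, negative
  expect_true(is.na(sig[1, 3]))  # never observed -> missing, not zero
  expect_equal(sig[2, 1], 0)
  expect_equal(sig[2, 2], 1)
  expect_true(all(sig[!is.na(sig)] >= 0 & sig[!is.na(sig)] <= 1))

  expect_error(feature_signature(asg, list(values = vals[1:3, ],
                                           mask = !is.na(vals[1:3, ]))),
               "rows")
})

test_that("coverage sums leading prevalences and checks its range", {
  Z <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2)
  asg <- assign_profiles(ibp_state(Z, matrix(0, 2, 2)),
                         method = "sampled_pattern")
  p <- length(asg$prevalence)
  expect_equal(coverage(asg, p), 1, tolerance = 1e-12)
  expect_equal(coverage(asg, 1), max(asg$prevalence))
  expect_error(coverage(asg, 0), "top_m")
  expect_error(coverage(asg, p + 1), "top_m")
})

test_that("the baseline profile has the lowest mean signature on synthetic data", {
  sc <- default_schema()
  sim <- simulate_ema_stream(
    cohort_config(n_patients = 20L, target_rows = c(pre = 700L, lockdown = 150L)),
    seed = 13)
  obs <- build_observation_matrix(sim$records, sc)
  # label rows by ground truth to isolate the signature computation
  truth_key <- paste(sim$truth$patient_id, sim$truth$date)
  row_key <- paste(obs$row_meta$patient_id, obs$row_meta$date)
  lab <- pmin(sim$truth$true_profile[match(row_key, truth_key)], 5L)
  fake <- structure(list(labels = match(lab, sort(unique(lab))),
                         patterns = NULL,
                         prevalence = prop.table(table(lab)),
                         n_rows = nrow(obs$values), method = "truth"),
                    class = "profile_assignment")
  sig <- feature_signature(fake, obs)
  means <- rowMeans(sig, na.rm = TRUE)
  expect_equal(unname(which.min(means[1:4])), 1)
  expect_true(all(means[1] <= means[2:4]))
})
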