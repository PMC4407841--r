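test_that("record-count formula holds across designs", {
  pars <- cohort_params()
  for (case in list(c(1, 5), c(2, 10), c(3, 7))) {
    d <- simulate_trial(pars, n_pairs = case[1], obs_per_period = case[2],
                        seed = 1)
    expect_equal(nrow(d), 2 * case[1] * case[2])
    # within every set: exactly two periods with opposite arms
    for (s in unique(d$set)) {
      ds <- d[d$set == s, ]
      expect_setequal(unique(ds$arm), c("active", "placebo"))
      expect_equal(length(unique(ds$period)), 2L)
      expect_equal(length(unique(ds$arm[ds$period == 1])), 1L)
    }
  }
  expect_error(simulate_trial(pars, n_pairs = 0), ">= 1")
})

test_that("degenerate noise gives exact arm means", {
  pars <- cohort_params(mu = 4, beta0 = 1.2, sigma_intercept = 0,
                        sigma_slope = 0, sigma_resid = 0)
  d <- simulate_trial(pars, n_pairs = 2, obs_per_period = 10, seed = 5)
  expect_true(all(d$outcome[d$arm == "placebo"] == 4))
  expect_true(all(d$outcome[d$arm == "active"] == 4 - 1.2))
})

test_that("simulated arm difference matches the generating effect", {
  pars <- cohort_params(beta0 = 1.75, sigma_resid = 1.5)
  d <- simulate_trial(pars, a_i = 0.4, b_i = 0.3, n_pairs = 2,
                      obs_per_period = 10, seed = 21)
  diff <- mean(d$outcome[d$arm == "placebo"]) -
    mean(d$outcome[d$arm == "active"])
  se <- 1.5 * sqrt(1 / 20 + 1 / 20)
  expect_lt(abs(diff - (1.75 + 0.3)), 3 * se)
})

test_that("cohort simulation respects design and stratification", {
  cohort <- simulate_cohort(seed = 3)
  expect_equal(length(unique(cohort$patient_id)), 30)
  tab <- table(unique(cohort[c("patient_id", "subgroup")])$subgroup)
  expect_equal(as.integer(tab[c("chloride", "sodium")]), c(15L, 15L))
  expect_equal(nrow(cohort), 30 * 40)
  # reproducibility
  expect_identical(simulate_cohort(seed = 3)$outcome, cohort$outcome)
})

test_that("zero random-effect SDs collapse patients to shared means", {
  cohort <- simulate_cohort(
    params = cohort_params(sigma_intercept = 0, sigma_slope = 0,
                           sigma_resid = 0),
    seed = 4)
  expect_equal(length(unique(cohort$outcome[cohort$arm == "placebo"])), 1L)
  expect_equal(length(unique(cohort$outcome[cohort$arm == "active"])), 1L)
})

test_that("grand mean of patient differences recovers beta0 (LLN oracle)", {
  means <- vapply(1:200, function(s)
    mean(raw_patient_diffs(simulate_cohort(seed = s))), 0)
  # var of one cohort mean ~ (sigma_b^2 + sigma^2 * 4/20) / 30
  mc_se <- sqrt((0.5^2 + 1.5^2 / 5) / 30 / 200)
  expect_lt(abs(mean(means) - 1.75), 4 * mc_se)
})

test_that("ordinal clipping clamps, rounds, and is idempotent", {
  expect_equal(clip_to_ivr(0.2), 1)
  expect_equal(clip_to_ivr(9.7), 9)
  expect_equal(clip_to_ivr(c(0.2, 5.4, 9.7), enabled = FALSE),
               c(0.2, 5.4, 9.7))
  v <- clip_to_ivr(rnorm(100, 5, 3))
  expect_identical(clip_to_ivr(v), v)
  expect_true(all(v %in% 1:9))
})

test_that("cost/effect simulator has the stated moments and determinism", {
  expect_error(simulate_cost_effect(10, correlation = 1.5), "correlation")
  z <- simulate_cost_effect(5, sd_cost = 0, sd_effect = 0, seed = 1)
  expect_true(all(z$cost[z$arm == "active"] == 2000))
  expect_true(all(z$effect[z$arm == "placebo"] == 0.70))
  big <- simulate_cost_effect(10000, sd_cost = 400, sd_effect = 0.05,
                              correlation = 0.3, seed = 2)
  act <- big[big$arm == "active", ]
  expect_lt(abs(mean(act$cost) - 2000), 3 * 400 / sqrt(10000))
  expect_lt(abs(mean(act$effect) - 0.75), 3 * 0.05 / sqrt(10000))
  expect_lt(abs(cor(act$cost, act$effect) - 0.3), 0.04)
  expect_identical(simulate_cost_effect(50, seed = 9),
                   simulate_cost_effect(50, seed = 9))
})
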