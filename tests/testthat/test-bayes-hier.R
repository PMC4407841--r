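# Model-fitting tests. Oracles: the closed-form normal-normal conjugate
# update (fixed variances), method-of-moments on raw patient differences,
# shrinkage bounds, and rjags as an independent MCMC cross-check.

test_that("single-patient sampler matches the conjugate closed form", {
  pars <- cohort_params(beta0 = 1.2, sigma_intercept = 0, sigma_slope = 0)
  d <- simulate_trial(pars, n_pairs = 2, obs_per_period = 10, seed = 42)
  sig <- 1.5
  fit <- fit_single_patient(d, prior = prior_normal(1.75, 0.89),
                            chains = 2, warmup = 500, iter = 12000,
                            seed = 3, fixed_sigma = sig)
  oracle <- conjugate_posterior(d$outcome[d$arm == "placebo"],
                                d$outcome[d$arm == "active"],
                                sig, 1.75, 0.89)
  b <- fit$draws[, "beta0"]
  expect_lt(abs(mean(b) - oracle$mean), 0.01)
  expect_lt(abs(sd(b) - oracle$sd), 0.01)

  # Gaussian-tail oracle for the posterior probability, to 2 decimals
  for (delta in c(0, 0.75, 1.5))
    expect_lt(abs(posterior_prob_at_least(fit, delta) -
                    (1 - pnorm((delta - oracle$mean) / oracle$sd))),
              0.015)
})

test_that("posterior_prob_at_least is a tail fraction, monotone in delta", {
  pars <- cohort_params(beta0 = 2)
  d <- simulate_trial(pars, seed = 8)
  fit <- fit_single_patient(d, seed = 2, iter = 2000)
  expect_equal(posterior_prob_at_least(fit, -Inf), 1)
  expect_equal(posterior_prob_at_least(fit, min(fit$draws[, "beta0"]) - 1), 1)
  deltas <- seq(-1, 4, by = 0.25)
  probs <- vapply(deltas, function(dd) posterior_prob_at_least(fit, dd), 0)
  expect_true(all(diff(probs) <= 0))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("flat-prior posterior mean agrees with method of moments and the frequentist fit", {
  cohort <- quick_cohort(seed = 31, n_patients = 20, obs = 10)
  fit <- fit_hierarchical(cohort, model_spec(prior_beta0 = prior_flat()),
                          chains = 2, warmup = 300, iter = 1000, seed = 6)
  b <- mean(fit$draws[, "beta0"])
  mom <- mean(raw_patient_diffs(cohort))
  expect_lt(abs(b - mom), 0.1)
  freq <- fit_crossover_frequentist(cohort)
  expect_lt(abs(b - freq$estimate), 0.1)
})

test_that("no-data limit returns the analysis prior", {
  # a patient whose residual SD is enormous carries no effect information
  d <- simulate_trial(cohort_params(beta0 = 0), n_pairs = 1,
                      obs_per_period = 5, seed = 2)
  fit <- fit_single_patient(d, prior = prior_normal(1.75, 0.89),
                            chains = 2, warmup = 500, iter = 15000,
                            seed = 4, fixed_sigma = 1e5)
  b <- fit$draws[, "beta0"]
  expect_equal(mean(b), 1.75, tolerance = 0.05)
  expect_equal(sd(b), 0.89, tolerance = 0.05)
})

test_that("shrinkage pulls patient effects between raw and population means", {
  cohort <- quick_cohort(seed = 12, n_patients = 8, obs = 8,
                         sigma_slope = 0.8)
  fit <- fit_hierarchical(cohort, model_spec(prior_beta0 = prior_flat(),
                                             subgroup_fixed_effect = FALSE),
                          chains = 2, warmup = 400, iter = 2000, seed = 9,
                          fixed = list(sigma_resid = 1.5))
  eff <- individual_effects(fit)
  raw <- raw_patient_diffs(cohort)
  pop <- mean(fit$draws[, "beta0"])
  slack <- 0.06  # Monte-Carlo slack on the bound
  for (i in seq_along(raw)) {
    lo <- min(raw[i], pop) - slack
    hi <- max(raw[i], pop) + slack
    expect_gte(eff$mean[i], lo)
    expect_lte(eff$mean[i], hi)
  }
  expect_true(all(eff$lower <= eff$mean & eff$mean <= eff$upper))
})

test_that("pooling limits: sigma_b -> 0 pools completely, large sigma_b does not pool", {
  cohort <- quick_cohort(seed = 13, n_patients = 6, obs = 10,
                         sigma_slope = 1)
  pooled <- fit_hierarchical(cohort,
                             model_spec(prior_beta0 = prior_flat(),
                                        subgroup_fixed_effect = FALSE),
                             chains = 2, warmup = 300, iter = 800, seed = 1,
                             fixed = list(sigma_slope = 0))
  eff_p <- individual_effects(pooled)
  expect_lt(max(abs(eff_p$mean - mean(pooled$draws[, "beta0"]))), 1e-9)

  unpooled <- fit_hierarchical(cohort,
                               model_spec(prior_beta0 = prior_flat(),
                                          subgroup_fixed_effect = FALSE),
                               chains = 2, warmup = 300, iter = 1500,
                               seed = 2,
                               fixed = list(sigma_slope = 50,
                                            sigma_resid = 1.5))
  eff_u <- individual_effects(unpooled)
  raw <- raw_patient_diffs(cohort)
  expect_lt(max(abs(eff_u$mean - raw)), 0.25)
})

test_that("input validation: empty data, one-armed patients, point priors", {
  expect_error(fit_hierarchical(data.frame()), "invalid input")
  cohort <- quick_cohort(seed = 5, n_patients = 4)
  solo <- cohort[!(cohort$patient_id == "P01" & cohort$arm == "active"), ]
  expect_warning(
    fit_hierarchical(solo, model_spec(), chains = 2, warmup = 200,
                     iter = 800, seed = 1),
    "single arm")
  expect_error(model_spec(prior_beta0 = prior_point(1)), "point-mass")
})

test_that("interaction terms require identifiable structure", {
  single_set <- quick_cohort(seed = 6, n_patients = 4, n_pairs = 1)
  expect_error(
    estimate_interactions(single_set,
                          model_spec(interaction_terms = "treatment_set")),
    "not estimable")
  # all-same-order data cannot identify the order interaction
  d <- quick_cohort(seed = 60, n_patients = 4)
  d$order <- "active_first"
  expect_error(
    estimate_interactions(d,
                          model_spec(interaction_terms = "treatment_order")),
    "not estimable")
})

test_that("interaction intervals cover zero when no interaction exists", {
  model <- model_spec(prior_beta0 = prior_flat(),
                      interaction_terms = c("treatment_set",
                                            "treatment_order"))
  hits <- vapply(1:100, function(s) {
    cohort <- quick_cohort(seed = 1000 + s, n_patients = 10, obs = 6)
    est <- suppressWarnings(
      estimate_interactions(cohort, model, chains = 2, warmup = 200,
                            iter = 400, seed = s))
    all(est$lower <= 0 & est$upper >= 0)
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("an injected order effect is recovered", {
  # build a cohort then shift active outcomes in placebo-first sets by a
  # known amount: order contrast is +/- 0.5 so the coefficient is 'shift'
  shift <- 0.8
  cohort <- quick_cohort(seed = 77, n_patients = 20, obs = 10)
  sel <- cohort$arm == "active" & cohort$order == "placebo_first"
  cohort$outcome[sel] <- cohort$outcome[sel] - shift
  est <- estimate_interactions(
    cohort, model_spec(prior_beta0 = prior_flat(),
                       interaction_terms = "treatment_order"),
    chains = 2, warmup = 300, iter = 800, seed = 3)
  expect_lt(abs(est$mean - shift), 3 * est$sd)
  expect_gt(est$mean, 0.2)
})

test_that("frequentist crossover matches a by-hand paired t computation", {
  d <- make_patient_series(list(list(placebo = c(5, 6, 7),
                                     active = c(3, 4, 5))))
  d2 <- make_patient_series(list(list(placebo = c(6, 6),
                                      active = c(5, 4))), "P02")
  d3 <- make_patient_series(list(list(placebo = c(4, 5, 6, 5),
                                      active = c(4, 4, 4, 4))), "P03")
  all3 <- rbind(d, d2, d3)
  res <- fit_crossover_frequentist(all3)
  diffs <- c(2, 1.5, 1)
  m <- mean(diffs); s <- sd(diffs); n <- 3
  tstat <- m / (s / sqrt(n))
  expect_equal(res$estimate, m, tolerance = 1e-3)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), n - 1), tolerance = 1e-3)
  expect_equal(res$conf_int,
               m + c(-1, 1) * qt(0.975, n - 1) * s / sqrt(n),
               tolerance = 1e-3)
  expect_true(res$conf_int[1] <= res$estimate &&
                res$estimate <= res$conf_int[2])

  zero <- make_patient_series(list(list(placebo = c(4, 4),
                                        active = c(4, 4))))
  zero2 <- make_patient_series(list(list(placebo = c(5, 5),
                                         active = c(5, 5))), "P02")
  expect_equal(fit_crossover_frequentist(rbind(zero, zero2))$estimate, 0)
  expect_error(fit_crossover_frequentist(d), ">= 2 patients")
})

test_that("hierarchical posterior agrees with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  cohort <- quick_cohort(seed = 91, n_patients = 8, obs = 8)
  fit <- fit_hierarchical(cohort,
                          model_spec(prior_beta0 = prior_normal(1.75, 0.89),
                                     subgroup_fixed_effect = FALSE),
                          chains = 2, warmup = 500, iter = 4000, seed = 2)
  model_str <- "
    model {
      for (j in 1:n) {
        y[j] ~ dnorm(mu + a[pid[j]] - trt[j] * (beta0 + b[pid[j]]), taue)
      }
      for (i in 1:N) {
        a[i] ~ dnorm(0, taua)
        b[i] ~ dnorm(0, taub)
      }
      mu ~ dnorm(0, 1e-4)
      beta0 ~ dnorm(1.75, pow(0.89, -2))
      taue ~ dgamma(0.01, 0.01)
      taua ~ dgamma(0.01, 0.01)
      taub ~ dgamma(0.01, 0.01)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = cohort$outcome,
                pid = as.integer(factor(cohort$patient_id)),
                trt = as.integer(cohort$arm == "active"),
                n = nrow(cohort),
                N = length(unique(cohort$patient_id))),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
  stats::update(jm, 1000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta0", n.iter = 4000,
                              progress.bar = "none")
  jb <- unlist(samp)
  b <- fit$draws[, "beta0"]
  expect_lt(abs(mean(b) - mean(jb)), 0.05)
  expect_lt(abs(sd(b) - sd(jb)), 0.05)
})

test_that("a near-Gaussian histogram prior matches its moment-matched normal", {
  # discretized Normal(1.75, 0.6) on a fine grid
  edges <- seq(-0.5, 4, by = 0.25)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  hist_prior <- make_histogram_prior(edges, dnorm(mids, 1.75, 0.6))
  norm_prior <- fit_normal_to_histogram(hist_prior)
  expect_equal(norm_prior$location, 1.75, tolerance = 1e-6)

  d <- simulate_trial(cohort_params(beta0 = 1.2), n_pairs = 2,
                      obs_per_period = 10, seed = 55)
  f_h <- fit_single_patient(d, prior = hist_prior, chains = 2,
                            warmup = 300, iter = 6000, seed = 1)
  f_n <- fit_single_patient(d, prior = norm_prior, chains = 2,
                            warmup = 300, iter = 6000, seed = 1)
  expect_lt(abs(mean(f_h$draws[, "beta0"]) - mean(f_n$draws[, "beta0"])),
            0.03)
  expect_lt(abs(sd(f_h$draws[, "beta0"]) - sd(f_n$draws[, "beta0"])), 0.03)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(1)
  good <- list(rnorm(1000), rnorm(1000))
  bad <- list(rnorm(1000), rnorm(1000, 3))
  expect_lt(split_rhat(good), 1.05)
  expect_gt(split_rhat(bad), 1.5)
})
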