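# Simulation-based assurance (expected posterior probability) sample-size
# calculation, the five-step procedure:
#   (1) draw a true mean effect from a truth prior;
#   (2) simulate the cohort of N-of-1 trials (random intercept, random
#       slope, within-person residual error; 2 x 10 x 2 observations per
#       trial by default);
#   (3) fit the hierarchical model with the analysis prior;
#   (4) take the marginal posterior of the population mean effect;
#   (5) record the posterior probability of an effect of at least the MCID.
# Iterating and averaging the probabilities gives the expected posterior
# probability of a clinically meaningful effect.

#' Assurance simulation specification
#'
#' Defaults reproduce the published design: 30 patients (15 chloride / 15
#' sodium), 2 completed treatment pairs, 10 observations per arm per pair,
#' truth and analysis priors Normal(1.75, 0.89), MCID 0.75, within-person
#' residual SD 1.5 and the documented default random-effect SDs (intercept
#' 1.0, slope 0.5).
#'
#' @param design a \code{\link{design_spec}}.
#' @param n_pairs completed treatment pairs per simulated patient.
#' @param truth_prior prior the true mean effect is drawn from (step 1); may
#'   be a \code{\link{prior_point}} for fixed-truth sensitivity runs.
#' @param analysis_prior prior used when fitting (step 3).
#' @param sim_params \code{\link{cohort_params}} fixing the variance
#'   components; its \code{beta0} is overwritten per iteration by the truth
#'   draw.
#' @param delta MCID threshold for the posterior probability (step 5).
#' @param n_iter number of iterations of steps 1-5.
#' @param seed master seed; per-iteration sub-seeds derive from it.
#' @param chains,warmup,iter MCMC effort per iteration's hierarchical fit
#'   (conjugate sampler, common residual variance by default).
#' @param residual_variance_mode passed to \code{\link{model_spec}};
#'   \code{"common"} is the fast default, \code{"per_patient"} available at
#'   higher cost.
#' @return an object of class \code{assurance_spec}.
#' @export
assurance_spec <- function(design = design_spec(), n_pairs = 2L,
                           truth_prior = prior_normal(1.75, 0.89),
                           analysis_prior = prior_normal(1.75, 0.89),
                           sim_params = cohort_params(),
                           delta = 0.75, n_iter = 1000L, seed = 1L,
                           chains = 2L, warmup = 300L, iter = 900L,
                           residual_variance_mode = "common") {
  stopifnot(inherits(design, "design_spec"),
            is_prior_spec(truth_prior), is_prior_spec(analysis_prior),
            inherits(sim_params, "cohort_params"))
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (n_pairs < 1) stop("invalid design: n_pairs must be >= 1", call. = FALSE)
  structure(list(design = design, n_pairs = as.integer(n_pairs),
                 truth_prior = truth_prior, analysis_prior = analysis_prior,
                 sim_params = sim_params, delta = delta,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter),
                 residual_variance_mode = residual_variance_mode),
            class = "assurance_spec")
}

#' Run the assurance (expected posterior probability) simulation
#'
#' Executes steps 1-5 for \code{spec$n_iter} iterations. Sub-seeds are drawn
#' once from the master seed, so the full run is bit-reproducible and
#' iterations are mutually independent. Iterations whose fit fails the
#' convergence gate (split R-hat on beta0 > 1.05) are re-run with a fresh
#' sub-seed and counted in \code{n_reruns}.
#'
#' @param spec an \code{\link{assurance_spec}}.
#' @param progress print a dot every 25 iterations.
#' @return an object of class \code{assurance_result}: per-iteration
#'   posterior probabilities, their mean (the expected posterior
#'   probability), Monte-Carlo standard error, rerun count, and an echo of
#'   the input \code{assurance_spec}.
#' @export
run_assurance <- function(spec = assurance_spec(), progress = FALSE) {
  stopifnot(inherits(spec, "assurance_spec"))
  sub_seeds <- withr_seed(spec$seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 2L * spec$n_iter),
           ncol = 2L)  # column 2 holds rerun reserve seeds
  })
  model <- model_spec(prior_beta0 = spec$analysis_prior,
                      subgroup_fixed_effect = TRUE,
                      residual_variance_mode = spec$residual_variance_mode)
  probs <- numeric(spec$n_iter)
  truths <- numeric(spec$n_iter)
  n_reruns <- 0L
  one_iter <- function(s) {
    beta_true <- withr_seed(s, prior_draw(spec$truth_prior, 1L))
    pars <- spec$sim_params
    pars$beta0 <- beta_true
    cohort <- simulate_cohort(spec$design, pars, n_pairs = spec$n_pairs,
                              seed = s %% .Machine$integer.max)
    fit <- suppressWarnings(
      fit_hierarchical(cohort, model, chains = spec$chains,
                       warmup = spec$warmup, iter = spec$iter, seed = s))
    list(prob = posterior_prob_at_least(fit, spec$delta),
         truth = beta_true, ok = fit$converged)
  }
  for (i in seq_len(spec$n_iter)) {
    res <- one_iter(sub_seeds[i, 1L])
    if (!res$ok) {
      n_reruns <- n_reruns + 1L
      res <- one_iter(sub_seeds[i, 2L])
    }
    probs[i] <- res$prob
    truths[i] <- res$truth
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(probs = probs, truths = truths, mean = mean(probs),
                 mcse = stats::sd(probs) / sqrt(spec$n_iter),
                 n_reruns = n_reruns, spec = spec, seed = spec$seed),
            class = "assurance_result")
}

#' @export
print.assurance_result <- function(x, ...) {
  cat(sprintf("Assurance: expected posterior probability %.3f (MCSE %.4f, %d iterations%s)\n",
              x$mean, x$mcse, length(x$probs),
              if (x$n_reruns) sprintf(", %d rerun(s)", x$n_reruns) else ""))
  invisible(x)
}

#' Summarize an assurance run
#'
#' @param result an \code{\link{run_assurance}} result.
#' @param probs_quantiles quantiles to report.
#' @return list: mean, median, quantiles, Monte-Carlo standard error, n.
#' @export
summarize_assurance <- function(result,
                                probs_quantiles = c(0.05, 0.25, 0.75, 0.95)) {
  stopifnot(inherits(result, "assurance_result"))
  p <- result$probs
  if (!length(p)) stop("invalid input: empty assurance result", call. = FALSE)
  list(mean = mean(p), median = stats::median(p),
       quantiles = stats::quantile(p, probs_quantiles),
       mcse = stats::sd(p) / sqrt(length(p)),
       n_iter = length(p), n_reruns = result$n_reruns)
}
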