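# Public model-fitting surface: hierarchical fit, single-patient fit,
# posterior probabilities, per-patient (shrunken) effects, interaction
# estimates and the frequentist crossover comparison.

validate_series <- function(data) {
  cols <- c("patient_id", "subgroup", "set", "period", "order", "arm",
            "day", "outcome")
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("invalid input: empty or non-tabular series", call. = FALSE)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("invalid input: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(data$arm %in% c("active", "placebo")))
    stop("invalid input: arm must be 'active' or 'placebo'", call. = FALSE)
  if (any(!is.finite(data$outcome)))
    stop("invalid input: non-finite outcome values", call. = FALSE)
  data
}

# Internal: map a series to the sampler's vectors.
prepare_model_data <- function(data, model) {
  data <- validate_series(data)
  pid_f <- factor(data$patient_id)
  pid <- as.integer(pid_f)
  trt <- as.integer(data$arm == "active")
  both <- tapply(trt, pid, function(z) any(z == 1) && any(z == 0))
  if (!any(both))
    stop("invalid input: no patient has observations in both arms",
         call. = FALSE)
  if (!all(both))
    warning("patient(s) with a single arm only: ",
            paste(levels(pid_f)[!both], collapse = ", "),
            "; their individual effects are prior-dominated", call. = FALSE)
  sub_pat <- tapply(as.character(data$subgroup), pid, `[`, 1L)
  x_pat <- if (model$subgroup_fixed_effect)
    subgroup_contrast(as.character(sub_pat)) else numeric(length(sub_pat))
  act <- trt == 1
  cset <- numeric(nrow(data))
  cord <- numeric(nrow(data))
  if ("treatment_set" %in% model$interaction_terms) {
    if (length(unique(data$set[act])) < 2L)
      stop("not estimable: treatment-by-set interaction needs >= 2 treatment sets",
           call. = FALSE)
    cset[act] <- data$set[act] - mean(data$set[act])
  }
  if ("treatment_order" %in% model$interaction_terms) {
    o <- ifelse(data$order == "active_first", -0.5, 0.5)
    if (length(unique(o[act])) < 2L)
      stop("not estimable: treatment-by-order interaction needs both period orders",
           call. = FALSE)
    cord[act] <- o[act] - mean(o[act])
  }
  list(y = as.numeric(data$outcome), pid = pid, trt = trt, x_pat = x_pat,
       cset = cset, cord = cord, patients = levels(pid_f),
       subgroup = as.character(sub_pat))
}

new_posterior_draws <- function(chain_draws, patients, model, seed,
                                warmup, mcid = 0.75) {
  chains <- length(chain_draws)
  iter <- nrow(chain_draws[[1L]])
  mat <- do.call(rbind, chain_draws)
  chain_id <- rep(seq_len(chains), each = iter)
  keep_cols <- colnames(mat)
  # drop structurally constant columns from the diagnostics table
  # (e.g. gamma_set when no interaction was requested)
  varying <- apply(mat, 2L, function(v) stats::var(v) > 0)
  diag_tab <- diagnose_params(mat[, varying, drop = FALSE], chain_id)
  # default acceptance gate: split R-hat < 1.05 and ESS >= 400 on the
  # population mean effect; failures warn and clear the flag, never pass
  # silently
  brow <- diag_tab[diag_tab$param == "beta0", ]
  conv_ok <- nrow(brow) == 1L && !is.na(brow$rhat) &&
    brow$rhat <= 1.05 && brow$ess >= 400
  if (nrow(brow) == 0L) conv_ok <- TRUE  # beta0 degenerate (fixed by prior)
  if (!conv_ok)
    warning(sprintf(
      "convergence flagged for beta0: split R-hat %.3f, ESS %.0f",
      brow$rhat, brow$ess), call. = FALSE)
  structure(list(draws = mat, chain = chain_id, patients = patients,
                 model = model, seed = seed, chains = chains,
                 iter = iter, warmup = warmup,
                 diagnostics = diag_tab, converged = conv_ok,
                 mcid = mcid),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  b <- x$draws[, "beta0"]
  cat(sprintf("Posterior draws: %d chains x %d iterations (%d total)\n",
              x$chains, x$iter, length(b)))
  cat(sprintf("  beta0 (population mean effect): mean %.3f, sd %.3f, 95%% CrI [%.3f, %.3f]\n",
              mean(b), stats::sd(b),
              stats::quantile(b, 0.025), stats::quantile(b, 0.975)))
  d <- x$diagnostics
  brow <- d[d$param == "beta0", ]
  if (nrow(brow))
    cat(sprintf("  diagnostics (beta0): split R-hat %.3f, ESS %.0f%s\n",
                brow$rhat, brow$ess,
                if (x$converged) "" else "  [CONVERGENCE FLAGGED]"))
  invisible(x)
}

#' Fit the hierarchical Bayesian model to combined N-of-1 data
#'
#' Posterior sampling (conjugate Gibbs) for the multi-level model with a
#' random intercept and random treatment slope per patient, an optional
#' centered subgroup fixed effect, optional treatment-by-set and
#' treatment-by-order interactions, and either a common residual variance or
#' per-patient residual variances drawn from a shared distribution. The
#' population mean effect beta0 carries the prior in
#' \code{model$prior_beta0}; all other location parameters get flat
#' (large-variance normal) priors and variances get weak inverse-gamma
#' hyperpriors.
#'
#' @param data an \code{nof1_series} (or equivalent long-format data frame).
#' @param model a \code{\link{model_spec}}.
#' @param chains,warmup,iter MCMC effort: number of chains, discarded warmup
#'   scans and kept iterations per chain.
#' @param seed integer seed (chain seeds derive from it deterministically).
#' @param fixed optional list fixing variance components at known values
#'   (\code{sigma_intercept}, \code{sigma_slope}, \code{sigma_resid});
#'   intended for conjugate checks and degenerate-noise tests.
#' @param mcid effect threshold recorded for downstream summaries.
#' @return an object of class \code{posterior_draws}: kept draws of beta0,
#'   mu, fixed-effect and interaction slopes, variance components and
#'   per-patient effects theta_i, with split R-hat and effective sample size
#'   per parameter. A split R-hat above 1.05 raises a convergence warning and
#'   clears the \code{converged} flag; it is never silently accepted.
#' @export
fit_hierarchical <- function(data, model = model_spec(), chains = 2L,
                             warmup = 500L, iter = 1500L, seed = 1L,
                             fixed = list(), mcid = 0.75) {
  stopifnot(inherits(model, "model_spec"))
  md <- prepare_model_data(data, model)
  chain_draws <- gibbs_nof1(md$y, md$pid, md$trt, md$x_pat, md$cset, md$cord,
                            model, chains = chains, warmup = warmup,
                            iter = iter, seed = seed, fixed = fixed)
  out <- new_posterior_draws(chain_draws, md$patients, model, seed, warmup,
                             mcid = mcid)
  out$subgroup <- md$subgroup
  out
}

#' Fit the single-patient model
#'
#' The within-patient model y = mu_i - theta * trt + eps with a flat prior on
#' the patient's level mu_i and the supplied prior on the effect theta; used
#' by the sequential interim analyses. Sampling is Gibbs; with a fixed
#' residual SD the posterior for theta is available in closed form
#' (normal-normal), which the sampler reproduces.
#'
#' @param data series for one patient (both arms present).
#' @param prior prior on the treatment effect (default flat, as interim
#'   analyses use non-informative priors only).
#' @param chains,warmup,iter,seed MCMC effort and seed.
#' @param fixed_sigma optionally fix the residual SD at a known value.
#' @return a \code{posterior_draws} whose \code{beta0} column holds theta.
#' @export
fit_single_patient <- function(data, prior = prior_flat(), chains = 2L,
                               warmup = 500L, iter = 2000L, seed = 1L,
                               fixed_sigma = NULL) {
  data <- validate_series(data)
  if (length(unique(data$patient_id)) != 1L)
    stop("invalid input: single-patient fit requires exactly one patient",
         call. = FALSE)
  if (prior$kind == "point")
    stop("a point-mass prior cannot be used as an analysis prior",
         call. = FALSE)
  y <- as.numeric(data$outcome)
  trt <- as.integer(data$arm == "active")
  if (!any(trt == 1) || !any(trt == 0))
    stop("invalid input: patient needs observations in both arms",
         call. = FALSE)
  hyper <- list(shape = 0.01, rate = 0.01)
  v_flat <- FLAT_PRIOR_SD^2
  n <- length(y)
  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    withr_seed(seed + 7907L * (ch - 1L), {
      mu <- mean(y) + stats::rnorm(1L, 0, 0.2)
      theta <- (mean(y[trt == 0]) - mean(y[trt == 1])) +
        stats::rnorm(1L, 0, 0.3)
      s2 <- if (!is.null(fixed_sigma)) fixed_sigma^2
            else max(stats::var(y), 0.05)
      keep <- matrix(NA_real_, iter, 3L,
                     dimnames = list(NULL, c("beta0", "mu", "sigma_resid")))
      for (it in seq_len(warmup + iter)) {
        # theta | s2, with mu integrated out exactly (collapsed draw; the
        # integrated log-likelihood is quadratic in theta, so three
        # evaluations recover its mean and precision) -- this removes the
        # mu-theta autocorrelation entirely
        int_ll <- function(th) {
          w <- y + trt * th            # active obs shifted to the mu scale
          wb <- mean(w)
          -sum((w - wb)^2) / (2 * s2) - wb^2 / (2 * (s2 / n + v_flat))
        }
        l0 <- int_ll(0); lp <- int_ll(1); lm <- int_ll(-1)
        curv <- (lp + lm - 2 * l0) / 2       # = -1/(2 * lik_var)
        lik_prec <- -2 * curv
        lik_mean <- (lp - lm) / 2 / lik_prec
        theta <- sample_beta0(prior, lik_mean, lik_prec)
        # mu | theta, s2
        r <- y + trt * theta
        prec <- n / s2 + 1 / v_flat
        mu <- stats::rnorm(1L, sum(r) / s2 / prec, sqrt(1 / prec))
        # s2
        if (is.null(fixed_sigma)) {
          e <- y - mu + trt * theta
          s2 <- rinvgamma1(hyper$shape + n / 2, hyper$rate + sum(e^2) / 2)
        }
        if (it > warmup)
          keep[it - warmup, ] <- c(theta, mu, sqrt(s2))
      }
      chain_draws[[ch]] <- keep
    })
  }
  new_posterior_draws(chain_draws, patients = unique(data$patient_id)[1L],
                      model = list(prior_beta0 = prior,
                                   single_patient = TRUE),
                      seed = seed, warmup = warmup)
}

#' Posterior probability of a treatment effect of at least delta
#'
#' Fraction of population-mean-effect draws at or above the threshold; with
#' the 0.75-point MCID this is the quantity driving both the interim
#' stopping rules and the assurance calculation.
#'
#' @param draws a \code{posterior_draws}.
#' @param delta effect threshold, score units.
#' @return probability in [0, 1].
#' @export
posterior_prob_at_least <- function(draws, delta) {
  stopifnot(inherits(draws, "posterior_draws"))
  b <- draws$draws[, "beta0"]
  if (!length(b)) stop("empty draws", call. = FALSE)
  mean(b >= delta)
}

#' Per-patient posterior effect summaries (shrinkage estimates)
#'
#' Each patient's effect theta_i = beta0 + beta_sub * x_i + b_i borrows
#' strength from the cohort: posterior means are pulled from the raw
#' within-patient differences toward the population mean in proportion to
#' within- vs between-patient variability.
#'
#' @param draws a fitted \code{posterior_draws} from
#'   \code{\link{fit_hierarchical}}.
#' @param delta effect threshold for the per-patient probability column
#'   (defaults to the MCID recorded at fit time).
#' @param level credible-interval level.
#' @return data frame: patient, posterior mean, sd, credible interval,
#'   P(effect >= delta).
#' @export
individual_effects <- function(draws, delta = draws$mcid, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  cols <- grep("^theta_", colnames(draws$draws), value = TRUE)
  if (!length(cols))
    stop("no per-patient effects in these draws", call. = FALSE)
  alpha <- (1 - level) / 2
  do.call(rbind, lapply(seq_along(cols), function(i) {
    th <- draws$draws[, cols[i]]
    data.frame(patient_id = draws$patients[i],
               mean = mean(th), sd = stats::sd(th),
               lower = stats::quantile(th, alpha, names = FALSE),
               upper = stats::quantile(th, 1 - alpha, names = FALSE),
               prob_ge_delta = mean(th >= delta),
               stringsAsFactors = FALSE)
  }))
}

#' Estimate treatment-by-set and treatment-by-order interactions
#'
#' Refits the hierarchical model with the requested interaction terms and
#' summarizes their posteriors. Structurally unidentifiable requests (a
#' single treatment set, or only one period order in the data) raise a
#' not-estimable error.
#'
#' @param data an \code{nof1_series}.
#' @param model a \code{\link{model_spec}} whose \code{interaction_terms} is
#'   non-empty.
#' @param ... passed to \code{\link{fit_hierarchical}}.
#' @return data frame of posterior summaries, one row per interaction term,
#'   with the fitted \code{posterior_draws} attached as attribute
#'   \code{"draws"}.
#' @export
estimate_interactions <- function(data, model, ...) {
  stopifnot(inherits(model, "model_spec"))
  if (!length(model$interaction_terms))
    stop("model has no interaction terms", call. = FALSE)
  fit <- fit_hierarchical(data, model, ...)
  rows <- lapply(model$interaction_terms, function(term) {
    col <- if (term == "treatment_set") "gamma_set" else "gamma_order"
    g <- fit$draws[, col]
    data.frame(term = term, mean = mean(g), sd = stats::sd(g),
               lower = stats::quantile(g, 0.025, names = FALSE),
               upper = stats::quantile(g, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- fit
  out
}

#' Frequentist crossover analysis of combined N-of-1 data
#'
#' The traditional comparator: each patient is reduced to the difference of
#' their placebo and active period means, and the differences are analyzed
#' with a paired (one-sample) t-test, as in the earlier crossover RCT.
#'
#' @param data an \code{nof1_series} with >= 2 patients, each observed on
#'   both arms.
#' @param level confidence level.
#' @return list of class \code{crossover_freq}: estimate, confidence
#'   interval, p-value, and the per-patient mean differences.
#' @export
fit_crossover_frequentist <- function(data, level = 0.95) {
  data <- validate_series(data)
  sp <- split(data, data$patient_id)
  diffs <- vapply(sp, function(d) {
    if (!any(d$arm == "active") || !any(d$arm == "placebo"))
      stop("invalid input: every patient needs both arms", call. = FALSE)
    mean(d$outcome[d$arm == "placebo"]) - mean(d$outcome[d$arm == "active"])
  }, 0)
  if (length(diffs) < 2L)
    stop("invalid input: need >= 2 patients for the crossover analysis",
         call. = FALSE)
  if (stats::sd(diffs) == 0) {
    est <- mean(diffs)
    res <- list(estimate = est, conf_int = c(est, est),
                p_value = if (est == 0) 1 else 0, diffs = diffs,
                level = level)
  } else {
    tt <- stats::t.test(diffs, conf.level = level)
    res <- list(estimate = unname(tt$estimate),
                conf_int = as.numeric(tt$conf.int),
                p_value = tt$p.value, diffs = diffs, level = level)
  }
  structure(res, class = "crossover_freq")
}

#' @export
print.crossover_freq <- function(x, ...) {
  cat(sprintf("Paired crossover analysis (%d patients)\n", length(x$diffs)))
  cat(sprintf("  mean difference (placebo - active): %.3f, %d%% CI [%.3f, %.3f], p = %.4g\n",
              x$estimate, round(100 * x$level), x$conf_int[1L],
              x$conf_int[2L], x$p_value))
  invisible(x)
}
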