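# Conjugate Gibbs sampler for the hierarchical N-of-1 model.
#
# Observation model (record j of patient i, trt = 1 on active arm):
#   y_ij = mu + a_i - trt_ij * (beta0 + beta_sub * x_i
#                               + g_set * cset_ij + g_ord * cord_ij + b_i)
#          + eps_ij,   eps_ij ~ N(0, s2_i)
#   a_i ~ N(0, sigma_a^2), b_i ~ N(0, sigma_b^2)
# Residual variance: common s2, or per-patient s2_i drawn from a shared
# scaled-inverse-chi-square distribution (nu, tau^2) with a gamma hyperprior
# on 1/tau^2's scale — "drawn from a common distribution".
# All mean-type updates are conjugate normals; variances are inverse-gamma.

#' Hierarchical model specification
#'
#' @param prior_beta0 \code{\link{prior_normal}}, \code{\link{prior_flat}} or
#'   \code{\link{prior_histogram}} on the population mean effect. Point-mass
#'   priors are rejected.
#' @param subgroup_fixed_effect include the centered chloride/sodium contrast
#'   as a fixed offset to the treatment effect (chloride -1/2, sodium +1/2,
#'   keeping beta0 the overall mean effect).
#' @param interaction_terms character subset of
#'   \code{c("treatment_set", "treatment_order")}: fixed treatment-by-set
#'   (centered set index) and treatment-by-order (centered order contrast)
#'   interaction slopes.
#' @param residual_variance_mode \code{"common"} (one residual variance) or
#'   \code{"per_patient"} (patient-specific variances under a shared
#'   hyperprior).
#' @param variance_hyper hyperprior settings: \code{shape}/\code{rate} of the
#'   inverse-gamma priors on the random-effect variances and the common
#'   residual variance; \code{nu} (degrees of freedom tying per-patient
#'   residual variances together) and \code{tau_shape}/\code{tau_rate}
#'   (gamma hyperprior on the shared scale) for the per-patient mode.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(prior_beta0 = prior_normal(1.75, 0.89),
                       subgroup_fixed_effect = TRUE,
                       interaction_terms = character(),
                       residual_variance_mode = c("common", "per_patient"),
                       variance_hyper = list()) {
  stopifnot(is_prior_spec(prior_beta0))
  if (prior_beta0$kind == "point")
    stop("a point-mass prior cannot be used as an analysis prior",
         call. = FALSE)
  residual_variance_mode <- match.arg(residual_variance_mode)
  bad <- setdiff(interaction_terms, c("treatment_set", "treatment_order"))
  if (length(bad))
    stop("unknown interaction term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hyper <- utils::modifyList(
    list(shape = 0.01, rate = 0.01, nu = 4, tau_shape = 1, tau_rate = 1),
    variance_hyper)
  structure(list(prior_beta0 = prior_beta0,
                 subgroup_fixed_effect = isTRUE(subgroup_fixed_effect),
                 interaction_terms = interaction_terms,
                 residual_variance_mode = residual_variance_mode,
                 variance_hyper = hyper),
            class = "model_spec")
}

# Sample beta0 from prior x N(lik_mean, lik_var) for any supported prior.
sample_beta0 <- function(prior, lik_mean, lik_prec) {
  if (prior$kind %in% c("normal", "flat")) {
    post_prec <- lik_prec + 1 / prior$scale^2
    post_mean <- (lik_mean * lik_prec + prior$location / prior$scale^2) /
      post_prec
    return(stats::rnorm(1L, post_mean, sqrt(1 / post_prec)))
  }
  # histogram: piecewise-constant prior times a normal likelihood gives a
  # mixture of truncated normals over the bins.
  s <- sqrt(1 / lik_prec)
  lo <- utils::head(prior$edges, -1L)
  hi <- prior$edges[-1L]
  plo <- stats::pnorm((lo - lik_mean) / s)
  phi <- stats::pnorm((hi - lik_mean) / s)
  mass <- prior$probs / (hi - lo) * pmax(phi - plo, 0)
  if (sum(mass) <= 0) {
    # likelihood concentrated outside the histogram support: take the
    # nearest supported bin
    k <- if (lik_mean <= lo[1L]) which(prior$probs > 0)[1L]
         else max(which(prior$probs > 0))
    return(stats::runif(1L, lo[k], hi[k]))
  }
  k <- sample.int(length(mass), 1L, prob = mass)
  u <- stats::runif(1L, plo[k], phi[k])
  lik_mean + s * stats::qnorm(min(max(u, 1e-12), 1 - 1e-12))
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape, rate = rate)

# Core sampler. Arguments are preprocessed vectors; returns per-chain draw
# matrices. Not exported; fit_hierarchical() is the public surface.
gibbs_nof1 <- function(y, pid, trt, x_pat, cset, cord, model,
                       chains = 2L, warmup = 500L, iter = 1500L,
                       seed = 1L, fixed = list()) {
  n <- length(y)
  N <- max(pid)
  hyper <- model$variance_hyper
  act <- trt == 1
  pid_act <- pid[act]
  n_i <- tabulate(pid, N)
  nact_i <- tabulate(pid_act, N)
  has_sub <- model$subgroup_fixed_effect && any(x_pat != 0)
  has_set <- "treatment_set" %in% model$interaction_terms
  has_ord <- "treatment_order" %in% model$interaction_terms
  x_rec <- x_pat[pid]            # record-level subgroup covariate
  per_patient <- model$residual_variance_mode == "per_patient"

  fix_sa <- fixed$sigma_intercept
  fix_sb <- fixed$sigma_slope
  fix_sr <- fixed$sigma_resid
  v_flat <- FLAT_PRIOR_SD^2      # proper flat prior variance for mu and
                                 # fixed-effect slopes
  psum <- function(v, idx, ng) {
    out <- numeric(ng)
    tmp <- rowsum(v, idx)
    out[as.integer(rownames(tmp))] <- tmp
    out
  }

  theta_names <- paste0("theta_", seq_len(N))
  scalar_names <- c("beta0", "mu", "beta_sub", "gamma_set", "gamma_order",
                    "sigma_a", "sigma_b", "sigma_resid")
  chain_draws <- vector("list", chains)

  for (ch in seq_len(chains)) {
    withr_seed(seed + 7907L * (ch - 1L), {
      # init, mildly overdispersed across chains
      mu <- mean(y) + stats::rnorm(1L, 0, 0.2)
      d0 <- mean(y[!act]) - mean(y[act])
      if (!is.finite(d0)) d0 <- 0
      beta0 <- d0 + stats::rnorm(1L, 0, 0.3)
      bs <- 0; gs <- 0; go <- 0
      a <- numeric(N); b <- numeric(N)
      sa2 <- if (!is.null(fix_sa)) fix_sa^2 else max(stats::var(y) / 2, 0.1)
      sb2 <- if (!is.null(fix_sb)) fix_sb^2 else 0.25
      s2_i <- rep(if (!is.null(fix_sr)) fix_sr^2
                  else max(stats::var(y) / 2, 0.1), N)
      tau2 <- s2_i[1L]

      keep <- matrix(NA_real_, iter, length(scalar_names) + N,
                     dimnames = list(NULL, c(scalar_names, theta_names)))
      total <- warmup + iter
      for (it in seq_len(total)) {
        w <- 1 / s2_i[pid]               # record-level precisions
        effvec <- beta0 + bs * x_rec + gs * cset + go * cord + b[pid]

        # mu
        r <- y - a[pid] + trt * effvec
        prec <- sum(w) + 1 / v_flat
        mu <- stats::rnorm(1L, sum(w * r) / prec, sqrt(1 / prec))

        # a_i
        if (is.null(fix_sa) || fix_sa > 0) {
          r <- y - mu + trt * effvec
          prec_i <- psum(w, pid, N) + 1 / sa2
          mean_i <- psum(w * r, pid, N) / prec_i
          a <- stats::rnorm(N, mean_i, sqrt(1 / prec_i))
        }

        # "observed total effect" on active records
        u <- (mu + a[pid] - y)[act]
        wa <- w[act]
        xa <- x_rec[act]; csa <- cset[act]; coa <- cord[act]

        # beta0
        resid <- u - (bs * xa + gs * csa + go * coa + b[pid_act])
        lik_prec <- sum(wa)
        beta0 <- sample_beta0(model$prior_beta0,
                              sum(wa * resid) / lik_prec, lik_prec)

        # subgroup fixed effect
        if (has_sub) {
          resid <- u - (beta0 + gs * csa + go * coa + b[pid_act])
          prec <- sum(wa * xa^2) + 1 / v_flat
          bs <- stats::rnorm(1L, sum(wa * xa * resid) / prec, sqrt(1 / prec))
        }

        # treatment x set / treatment x order interactions
        if (has_set) {
          resid <- u - (beta0 + bs * xa + go * coa + b[pid_act])
          prec <- sum(wa * csa^2) + 1 / v_flat
          gs <- stats::rnorm(1L, sum(wa * csa * resid) / prec, sqrt(1 / prec))
        }
        if (has_ord) {
          resid <- u - (beta0 + bs * xa + gs * csa + b[pid_act])
          prec <- sum(wa * coa^2) + 1 / v_flat
          go <- stats::rnorm(1L, sum(wa * coa * resid) / prec, sqrt(1 / prec))
        }

        # b_i
        if (is.null(fix_sb) || fix_sb > 0) {
          resid <- u - (beta0 + bs * xa + gs * csa + go * coa)
          prec_i <- psum(wa, pid_act, N) + 1 / sb2
          mean_i <- psum(wa * resid, pid_act, N) / prec_i
          b <- stats::rnorm(N, mean_i, sqrt(1 / prec_i))
        }

        # recentering (translation) moves along the (mu, a) and (beta0, b)
        # ridges: shifting (mu + c, a - c) leaves the likelihood invariant,
        # so c has a conjugate normal conditional from the priors alone;
        # these interweaving steps decorrelate the fixed effects from the
        # random-effect means and sharply improve mixing
        if (is.null(fix_sa) || fix_sa > 0) {
          prec <- 1 / v_flat + N / sa2
          cc <- stats::rnorm(1L, (-mu / v_flat + sum(a) / sa2) / prec,
                             sqrt(1 / prec))
          mu <- mu + cc; a <- a - cc
        }
        if ((is.null(fix_sb) || fix_sb > 0) &&
            model$prior_beta0$kind != "histogram") {
          pv <- model$prior_beta0$scale^2
          pm <- model$prior_beta0$location
          prec <- 1 / pv + N / sb2
          cc <- stats::rnorm(1L, ((pm - beta0) / pv + sum(b) / sb2) / prec,
                             sqrt(1 / prec))
          beta0 <- beta0 + cc; b <- b - cc
        }

        # random-effect variances
        if (is.null(fix_sa))
          sa2 <- rinvgamma1(hyper$shape + N / 2, hyper$rate + sum(a^2) / 2)
        if (is.null(fix_sb))
          sb2 <- rinvgamma1(hyper$shape + N / 2, hyper$rate + sum(b^2) / 2)

        # residual variance(s)
        if (is.null(fix_sr)) {
          effvec <- beta0 + bs * x_rec + gs * cset + go * cord + b[pid]
          e <- y - mu - a[pid] + trt * effvec
          if (per_patient) {
            rss_i <- psum(e^2, pid, N)
            s2_i <- 1 / stats::rgamma(N, hyper$nu / 2 + n_i / 2,
                                      rate = hyper$nu * tau2 / 2 + rss_i / 2)
            # tau2 enters each s2_i's inverse-gamma rate linearly, so its
            # gamma prior is conjugate
            tau2 <- stats::rgamma(1L, hyper$tau_shape + N * hyper$nu / 2,
                                  rate = hyper$tau_rate +
                                    hyper$nu * sum(1 / s2_i) / 2)
          } else {
            s2 <- rinvgamma1(hyper$shape + n / 2, hyper$rate + sum(e^2) / 2)
            s2_i <- rep(s2, N)
          }
        }

        if (it > warmup) {
          k <- it - warmup
          keep[k, ] <- c(beta0, mu, bs, gs, go, sqrt(sa2), sqrt(sb2),
                         sqrt(if (per_patient) tau2 else s2_i[1L]),
                         beta0 + bs * x_pat + b)
        }
      }
      chain_draws[[ch]] <- keep
    })
  }
  chain_draws
}
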