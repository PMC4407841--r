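# Synthetic diary-data generator for N-of-1 series: per-patient random
# intercept a_i, random treatment slope b_i, within-person residual noise.
# Sign convention (fixed package-wide): a positive treatment effect means the
# active arm LOWERS the severity score, so active outcomes are generated by
# subtracting the effect.

#' Cohort-level data-generating parameters
#'
#' Placebo observations are Normal(mu + a_i, resid_sd_i); active observations
#' are Normal(mu + a_i - (beta0 + beta_subgroup * x_i + b_i), resid_sd_i),
#' with a_i ~ Normal(0, sigma_intercept^2), b_i ~ Normal(0, sigma_slope^2)
#' and x_i the centered subgroup contrast (chloride -1/2, sodium +1/2).
#'
#' Defaults: \code{mu = 4.21} (the placebo-arm mean severity reported for the
#' earlier crossover RCT), \code{sigma_resid = 1.5} (the reported
#' within-subject SD), \code{sigma_intercept = 1}, \code{sigma_slope = 0.5}.
#'
#' @param mu mean outcome level on placebo (score units).
#' @param beta0 mean treatment effect; positive = severity reduction.
#' @param beta_subgroup subgroup offset to the treatment effect.
#' @param sigma_intercept SD of per-patient intercepts.
#' @param sigma_slope SD of per-patient treatment-effect deviations.
#' @param sigma_resid within-person residual SD.
#' @param resid_heterogeneity optional spread for patient-specific residual
#'   SDs: each patient's residual SD is drawn log-normally around
#'   \code{sigma_resid} with this SD on the log scale; 0 = common residual SD.
#' @return an object of class \code{cohort_params}.
#' @export
cohort_params <- function(mu = 4.21, beta0 = 1.75, beta_subgroup = 0,
                          sigma_intercept = 1, sigma_slope = 0.5,
                          sigma_resid = 1.5, resid_heterogeneity = 0) {
  sds <- c(sigma_intercept, sigma_slope, sigma_resid, resid_heterogeneity)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all SD parameters must be finite and >= 0", call. = FALSE)
  structure(list(mu = mu, beta0 = beta0, beta_subgroup = beta_subgroup,
                 sigma_intercept = sigma_intercept,
                 sigma_slope = sigma_slope, sigma_resid = sigma_resid,
                 resid_heterogeneity = resid_heterogeneity),
            class = "cohort_params")
}

new_nof1_series <- function(df) {
  cols <- c("patient_id", "subgroup", "set", "period", "order", "arm",
            "day", "outcome")
  stopifnot(all(cols %in% names(df)))
  df <- df[, cols]
  class(df) <- c("nof1_series", "data.frame")
  df
}

#' @export
print.nof1_series <- function(x, ...) {
  cat(sprintf("N-of-1 series: %d observations, %d patient(s), %d set(s)\n",
              nrow(x), length(unique(x$patient_id)),
              length(unique(x$set))))
  NextMethod()
}

#' Simulate one patient's N-of-1 trial
#'
#' Generates \code{2 * obs_per_period * n_pairs} diary observations for a
#' single patient with known individual effects: placebo outcomes are
#' Normal(mu + a_i, resid_sd), active outcomes are
#' Normal(mu + a_i - (beta0 + beta_subgroup * x + b_i), resid_sd).
#'
#' @param params a \code{\link{cohort_params}}.
#' @param a_i patient's random intercept.
#' @param b_i patient's treatment-effect deviation.
#' @param resid_sd patient's residual SD (defaults to
#'   \code{params$sigma_resid}).
#' @param n_pairs number of completed treatment pairs (sets).
#' @param obs_per_period diary observations per period.
#' @param orders a \code{\link{randomize_orders}} result with at least
#'   \code{n_pairs} labels, or \code{NULL} to randomize internally.
#' @param seed integer seed.
#' @param patient_id,subgroup identifiers stamped onto the records;
#'   \code{subgroup_x} is the centered subgroup contrast used for the
#'   subgroup effect term.
#' @param subgroup_x centered subgroup covariate (chloride -0.5, sodium 0.5).
#' @param clip clamp outcomes to the ordinal 1--9 diary scale
#'   (\code{\link{clip_to_ivr}}); off by default, matching the normal model.
#' @return an \code{nof1_series} data frame.
#' @export
simulate_trial <- function(params, a_i = 0, b_i = 0,
                           resid_sd = params$sigma_resid,
                           n_pairs = 2L, obs_per_period = 10L,
                           orders = NULL, seed = 1L,
                           patient_id = "P01", subgroup = "chloride",
                           subgroup_x = 0, clip = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  if (n_pairs < 1 || obs_per_period < 1)
    stop("n_pairs and obs_per_period must be >= 1", call. = FALSE)
  n_pairs <- as.integer(n_pairs)
  obs_per_period <- as.integer(obs_per_period)
  withr_seed(seed, {
    if (is.null(orders)) {
      order_labels <- sample(c("active_first", "placebo_first"), n_pairs,
                             replace = TRUE)
    } else {
      stopifnot(inherits(orders, "period_order"),
                length(orders$labels) >= n_pairs)
      order_labels <- orders$labels[seq_len(n_pairs)]
    }
    effect <- params$beta0 + params$beta_subgroup * subgroup_x + b_i
    recs <- lapply(seq_len(n_pairs), function(s) {
      arms <- if (order_labels[s] == "active_first")
        c("active", "placebo") else c("placebo", "active")
      do.call(rbind, lapply(1:2, function(p) {
        arm <- arms[p]
        m <- params$mu + a_i - if (arm == "active") effect else 0
        data.frame(patient_id = patient_id, subgroup = subgroup,
                   set = s, period = p, order = order_labels[s],
                   arm = arm, day = seq_len(obs_per_period),
                   outcome = stats::rnorm(obs_per_period, m, resid_sd),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, recs)
    if (clip) out$outcome <- clip_to_ivr(out$outcome)
    new_nof1_series(out)
  })
}

#' Simulate a cohort of N-of-1 trials
#'
#' Draws per-patient effects a_i ~ Normal(0, sigma_intercept^2) and
#' b_i ~ Normal(0, sigma_slope^2), assigns subgroups per
#' \code{design$subgroup_split}, block-randomizes period order per set, and
#' simulates each patient's diary series.
#'
#' @param design a \code{\link{design_spec}}.
#' @param params a \code{\link{cohort_params}}.
#' @param n_pairs completed treatment pairs per patient.
#' @param seed integer master seed.
#' @param obs_per_period observations per arm per pair; defaults to
#'   \code{design$obs_per_arm_per_pair}.
#' @param clip clamp outcomes to the 1--9 ordinal scale.
#' @return an \code{nof1_series} covering all patients, with the generating
#'   effects attached as attribute \code{"patient_effects"}.
#' @export
simulate_cohort <- function(design = design_spec(), params = cohort_params(),
                            n_pairs = 2L, seed = 1L,
                            obs_per_period = design$obs_per_arm_per_pair,
                            clip = FALSE) {
  stopifnot(inherits(design, "design_spec"), inherits(params, "cohort_params"))
  subgroups <- rep(names(design$subgroup_split), design$subgroup_split)
  n <- design$n_patients
  withr_seed(seed, {
    a <- stats::rnorm(n, 0, params$sigma_intercept)
    b <- stats::rnorm(n, 0, params$sigma_slope)
    resid_sd <- if (params$resid_heterogeneity > 0)
      params$sigma_resid * exp(stats::rnorm(n, 0, params$resid_heterogeneity) -
                                 params$resid_heterogeneity^2 / 2)
    else rep(params$sigma_resid, n)
    # centered contrast keeps beta0 the overall mean effect
    xs <- subgroup_contrast(subgroups)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    series <- lapply(seq_len(n), function(i) {
      simulate_trial(params, a_i = a[i], b_i = b[i], resid_sd = resid_sd[i],
                     n_pairs = n_pairs, obs_per_period = obs_per_period,
                     seed = sub_seeds[i],
                     patient_id = sprintf("P%02d", i),
                     subgroup = subgroups[i], subgroup_x = xs[i],
                     clip = clip)
    })
    out <- new_nof1_series(do.call(rbind, series))
    attr(out, "patient_effects") <- data.frame(
      patient_id = sprintf("P%02d", seq_len(n)), subgroup = subgroups,
      a_i = a, b_i = b, resid_sd = resid_sd,
      effect = params$beta0 + params$beta_subgroup * xs + b,
      stringsAsFactors = FALSE)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

# Centered +/- 1/2 coding for a two-level subgroup factor; a single level
# maps to 0 (no subgroup term estimable).
subgroup_contrast <- function(subgroup) {
  lev <- sort(unique(subgroup))
  if (length(lev) == 1L) return(rep(0, length(subgroup)))
  if (length(lev) > 2L)
    stop("subgroup must have at most two levels", call. = FALSE)
  ifelse(subgroup == lev[1L], -0.5, 0.5)
}

#' Clamp outcomes to the ordinal 1--9 diary scale
#'
#' When enabled, rounds to the nearest integer and clamps into [1, 9]
#' (idempotent); when disabled, returns the input unchanged.
#'
#' @param values numeric outcomes.
#' @param enabled apply the clipping.
#' @return numeric vector.
#' @export
clip_to_ivr <- function(values, enabled = TRUE) {
  if (!enabled) return(values)
  pmin(9, pmax(1, round(values)))
}

#' Simulate paired cost/effect records for the cost-effectiveness layer
#'
#' Per-patient bivariate (cost, effect) pairs per arm, normal with the stated
#' means, SDs and within-patient cost-effect correlation.
#'
#' @param n_patients patients per arm (paired: every patient has both arms).
#' @param mean_cost named vector \code{c(active = , placebo = )}, currency.
#' @param mean_effect named vector \code{c(active = , placebo = )}, QoL units.
#' @param sd_cost,sd_effect noise SDs (scalar, shared by arms).
#' @param correlation cost-effect correlation within patient-arm, in [-1, 1].
#' @param seed integer seed.
#' @return a data frame of class \code{cost_effect_records} with columns
#'   patient_id, arm, cost, effect.
#' @export
simulate_cost_effect <- function(n_patients,
                                 mean_cost = c(active = 2000, placebo = 1500),
                                 mean_effect = c(active = 0.75, placebo = 0.70),
                                 sd_cost = 400, sd_effect = 0.05,
                                 correlation = 0.2, seed = 1L) {
  if (sd_cost < 0 || sd_effect < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (!is.finite(correlation) || abs(correlation) > 1)
    stop("correlation must lie in [-1, 1]", call. = FALSE)
  stopifnot(all(c("active", "placebo") %in% names(mean_cost)),
            all(c("active", "placebo") %in% names(mean_effect)))
  withr_seed(seed, {
    recs <- lapply(c("active", "placebo"), function(arm) {
      z1 <- stats::rnorm(n_patients)
      z2 <- correlation * z1 + sqrt(1 - correlation^2) * stats::rnorm(n_patients)
      data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                 arm = arm,
                 cost = mean_cost[[arm]] + sd_cost * z1,
                 effect = mean_effect[[arm]] + sd_effect * z2,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    class(out) <- c("cost_effect_records", "data.frame")
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
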