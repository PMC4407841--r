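# Per-patient sequential interim analyses after treatment sets 1-3.

#' Sequential stopping rule
#'
#' Default thresholds follow the protocol: advise stopping for effectiveness
#' when the posterior probability of an effect larger than the 0.75-point
#' MCID is at least 80\%, stopping for ineffectiveness when it is at most
#' 20\%, and continuing otherwise. Interim analyses use non-informative
#' priors only, so the stopping advice rests on the patient's own data.
#'
#' @param delta MCID threshold, score units.
#' @param upper posterior-probability bound for stop-effective (inclusive).
#' @param lower posterior-probability bound for stop-ineffective (inclusive).
#' @param max_sets maximum number of treatment sets.
#' @param interim_prior prior used at interim fits (flat by default; an
#'   informative prior here would contradict the design and is rejected by
#'   \code{\link{run_sequential}}).
#' @return an object of class \code{stopping_rule}.
#' @export
stopping_rule <- function(delta = 0.75, upper = 0.80, lower = 0.20,
                          max_sets = 4L, interim_prior = prior_flat()) {
  stopifnot(is.numeric(delta), is.numeric(upper), is.numeric(lower))
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  stopifnot(is_prior_spec(interim_prior))
  structure(list(delta = delta, upper = upper, lower = lower,
                 max_sets = as.integer(max_sets),
                 interim_prior = interim_prior),
            class = "stopping_rule")
}

#' Map a posterior probability to an interim decision
#'
#' Boundaries are inclusive ("at least 80\%", "at most 20\%").
#'
#' @param prob posterior probability of an effect of at least
#'   \code{rule$delta}, in [0, 1].
#' @param rule a \code{\link{stopping_rule}}.
#' @param set_index treatment set the decision follows (recorded).
#' @return an object of class \code{interim_decision}: list with
#'   \code{decision} in \{stop_effective, stop_ineffective, continue\},
#'   \code{prob} and \code{set}.
#' @export
interim_decision <- function(prob, rule = stopping_rule(), set_index = NA) {
  stopifnot(inherits(rule, "stopping_rule"))
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob < 0 || prob > 1)
    stop("prob must be a probability in [0, 1]", call. = FALSE)
  decision <- if (prob >= rule$upper) "stop_effective"
              else if (prob <= rule$lower) "stop_ineffective"
              else "continue"
  structure(list(decision = decision, prob = prob, set = set_index),
            class = "interim_decision")
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("Interim decision (after set %s): %s  [P(effect >= delta) = %.3f]\n",
              as.character(x$set), x$decision, x$prob))
  invisible(x)
}

#' Run the sequential interim analyses for one patient
#'
#' Fits the single-patient model with the non-informative interim prior on
#' the cumulative data after each completed treatment set (sets 1 up to 3),
#' emitting a decision per analysis and stopping at the first stop decision.
#' No interim decision is ever emitted after set 4: the final set's data flow
#' only into the combined analysis. Sets missing one of their two periods
#' are excluded with a warning.
#'
#' @param series an \code{nof1_series} for a single patient, ordered by set.
#' @param rule a \code{\link{stopping_rule}}; its prior must be flat.
#' @param chains,warmup,iter,seed MCMC effort per interim fit.
#' @return list of \code{interim_decision}, at most
#'   \code{min(3, completed sets)} long.
#' @export
run_sequential <- function(series, rule = stopping_rule(), chains = 2L,
                           warmup = 300L, iter = 1200L, seed = 1L) {
  stopifnot(inherits(rule, "stopping_rule"))
  if (rule$interim_prior$kind != "flat")
    stop("interim analyses use non-informative priors only", call. = FALSE)
  series <- validate_series(series)
  if (length(unique(series$patient_id)) != 1L)
    stop("run_sequential takes a single patient's series", call. = FALSE)
  sets <- sort(unique(series$set))
  complete <- vapply(sets, function(s) {
    d <- series[series$set == s, ]
    any(d$arm == "active") && any(d$arm == "placebo")
  }, TRUE)
  if (any(!complete)) {
    warning("excluding incomplete set(s): ",
            paste(sets[!complete], collapse = ", "), call. = FALSE)
    sets <- sets[complete]
  }
  if (!length(sets))
    stop("invalid input: no complete treatment set", call. = FALSE)
  n_interim <- min(3L, length(sets), rule$max_sets - 1L)
  decisions <- list()
  for (k in seq_len(n_interim)) {
    cum <- series[series$set %in% sets[seq_len(k)], ]
    fit <- fit_single_patient(cum, prior = rule$interim_prior,
                              chains = chains, warmup = warmup, iter = iter,
                              seed = seed + k)
    p <- posterior_prob_at_least(fit, rule$delta)
    dec <- interim_decision(p, rule, set_index = sets[k])
    decisions[[k]] <- dec
    if (dec$decision != "continue") break
  }
  decisions
}
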