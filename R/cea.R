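# Cost-effectiveness layer: resource volumes x unit costs, the incremental
# cost-effectiveness ratio with dominance handling, and nonparametric
# (percentile) bootstrap intervals. Currency is a label (default EUR, price
# year 2014); no conversion logic.

#' Unit-cost table
#'
#' @param costs named numeric vector: resource category -> unit cost.
#' @param currency currency label.
#' @param price_year price-year label.
#' @return an object of class \code{unit_cost_table}.
#' @export
unit_cost_table <- function(costs, currency = "EUR", price_year = "2014") {
  if (is.null(names(costs)) || any(!nzchar(names(costs))))
    stop("unit costs must be named by resource category", call. = FALSE)
  if (anyDuplicated(names(costs)))
    stop("duplicate resource categories", call. = FALSE)
  if (any(costs < 0)) stop("unit costs must be >= 0", call. = FALSE)
  structure(list(costs = costs, currency = currency,
                 price_year = price_year),
            class = "unit_cost_table")
}

#' Total cost from resource volumes and unit costs
#'
#' Per-patient costs are resource volumes multiplied by unit costs, summed
#' over categories; additive over disjoint volume sets.
#'
#' @param volumes named numeric vector: category -> quantity consumed.
#' @param unit_costs a \code{\link{unit_cost_table}} or named numeric vector.
#' @return total cost (currency units). Empty volumes cost 0.
#' @examples
#' compute_costs(c(visits = 2, admission_days = 1),
#'               c(visits = 50, admission_days = 300))  # 400
#' @export
compute_costs <- function(volumes, unit_costs) {
  if (inherits(unit_costs, "unit_cost_table")) unit_costs <- unit_costs$costs
  if (length(volumes) == 0L) return(0)
  if (is.null(names(volumes)))
    stop("volumes must be named by resource category", call. = FALSE)
  missing_cat <- setdiff(names(volumes), names(unit_costs))
  if (length(missing_cat))
    stop("missing unit cost for categor",
         if (length(missing_cat) > 1L) "ies: " else "y: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  sum(volumes * unit_costs[names(volumes)])
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' The ICER (difference in mean costs over difference in mean effects,
#' new vs comparator) is only meaningful when the new treatment is more
#' effective and more expensive, or less effective and less expensive; when
#' one option is both cheaper and more effective the result is a dominance
#' flag, and a zero effect difference yields an undefined-ICER flag.
#'
#' @param delta_cost incremental mean cost (new minus comparator), currency.
#' @param delta_effect incremental mean effect (new minus comparator), QoL
#'   units.
#' @return list of class \code{icer_result}: \code{kind} in
#'   \{\code{"icer"}, \code{"dominant"}, \code{"dominated"},
#'   \code{"undefined"}\}, and \code{value} (the ratio, or \code{NA} for
#'   flags), plus the inputs.
#' @export
icer <- function(delta_cost, delta_effect) {
  kind <- if (delta_effect == 0) "undefined"
          else if (delta_cost <= 0 && delta_effect > 0) "dominant"
          else if (delta_cost > 0 && delta_effect < 0) "dominated"
          else "icer"
  structure(list(kind = kind,
                 value = if (kind == "icer") delta_cost / delta_effect
                         else NA_real_,
                 delta_cost = delta_cost, delta_effect = delta_effect),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  msg <- switch(x$kind,
    icer = sprintf("ICER: %.2f per effect unit", x$value),
    dominant = "new treatment dominates (cheaper and more effective)",
    dominated = "new treatment dominated (more expensive, less effective)",
    undefined = "ICER undefined (zero effect difference)")
  cat(msg, "\n")
  invisible(x)
}

#' Nonparametric bootstrap intervals for costs, effects and the ICER
#'
#' Patients are resampled with replacement within arm; percentile intervals
#' (default 95\%) are computed for the mean cost difference and mean effect
#' difference (active minus placebo). The ICER interval is reported only when
#' every resample falls in a sign-concordant (ICER-meaningful) quadrant;
#' otherwise it is suppressed with an explanatory flag while the cost and
#' effect intervals are still returned.
#'
#' @param records a \code{cost_effect_records} data frame (columns
#'   patient_id, arm, cost, effect) with >= 2 patients per arm.
#' @param n_boot bootstrap resamples, >= 100.
#' @param seed integer seed.
#' @param level interval level.
#' @return list of class \code{bootstrap_ce}: point estimates, percentile
#'   intervals, the ICER interval or suppression flag, and the seed.
#' @export
bootstrap_ce <- function(records, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "arm", "cost", "effect") %in% names(records)))
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  act <- records[records$arm == "active", ]
  plc <- records[records$arm == "placebo", ]
  if (nrow(act) < 2L || nrow(plc) < 2L)
    stop("invalid input: need >= 2 patients per arm", call. = FALSE)
  dc_hat <- mean(act$cost) - mean(plc$cost)
  de_hat <- mean(act$effect) - mean(plc$effect)
  alpha <- (1 - level) / 2
  withr_seed(seed, {
    na <- nrow(act); np <- nrow(plc)
    dc <- numeric(n_boot); de <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      ia <- sample.int(na, na, replace = TRUE)
      ip <- sample.int(np, np, replace = TRUE)
      dc[b] <- mean(act$cost[ia]) - mean(plc$cost[ip])
      de[b] <- mean(act$effect[ia]) - mean(plc$effect[ip])
    }
    ci <- function(v) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    concordant <- (dc > 0 & de > 0) | (dc < 0 & de < 0)
    icer_ci <- NULL
    icer_flag <- NULL
    if (all(concordant)) {
      icer_ci <- ci(dc / de)
    } else {
      icer_flag <- sprintf(
        "ICER interval suppressed: %d of %d resamples fall in sign-mixed (dominance or undefined) quadrants",
        sum(!concordant), n_boot)
    }
    structure(list(delta_cost = dc_hat, delta_effect = de_hat,
                   delta_cost_ci = ci(dc), delta_effect_ci = ci(de),
                   icer = icer(dc_hat, de_hat),
                   icer_ci = icer_ci, icer_flag = icer_flag,
                   level = level, n_boot = as.integer(n_boot),
                   seed = as.integer(seed)),
              class = "bootstrap_ce")
  })
}

#' @export
print.bootstrap_ce <- function(x, ...) {
  pct <- round(100 * x$level)
  cat(sprintf("Bootstrap CE analysis (%d resamples)\n", x$n_boot))
  cat(sprintf("  mean cost difference:   %.2f, %d%% CI [%.2f, %.2f]\n",
              x$delta_cost, pct, x$delta_cost_ci[1L], x$delta_cost_ci[2L]))
  cat(sprintf("  mean effect difference: %.4f, %d%% CI [%.4f, %.4f]\n",
              x$delta_effect, pct, x$delta_effect_ci[1L],
              x$delta_effect_ci[2L]))
  if (!is.null(x$icer_ci))
    cat(sprintf("  ICER: %.2f, %d%% CI [%.2f, %.2f]\n", x$icer$value, pct,
                x$icer_ci[1L], x$icer_ci[2L]))
  else if (!is.null(x$icer_flag)) cat(" ", x$icer_flag, "\n")
  invisible(x)
}
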