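# Histogram-based expert prior elicitation and linear opinion pooling into a
# group clinical prior.

#' Build a histogram prior from elicited bin weights
#'
#' Each expert distributes weight (e.g. chips or probability points) over a
#' common grid of effect-size bins; weights are normalized to a probability
#' histogram.
#'
#' @param edges strictly increasing bin edges (score units).
#' @param weights non-negative elicited weights, not all zero; one per bin.
#' @return a \code{\link{prior_histogram}}.
#' @examples
#' make_histogram_prior(c(0, 1, 2, 3), c(1, 1, 2))$probs  # 0.25 0.25 0.50
#' @export
make_histogram_prior <- function(edges, weights) {
  if (length(weights) < 1L) stop("need >= 1 bin", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  tot <- sum(weights)
  if (tot <= 0) stop("weights must not all be zero", call. = FALSE)
  prior_histogram(edges, weights / tot)
}

#' Pool expert histogram priors into one group clinical prior
#'
#' Linear (arithmetic) opinion pool on a common grid: the pooled probability
#' of each bin is the expert-weighted average of the experts' bin
#' probabilities. Equal expert weights by default.
#'
#' @param priors list of histogram \code{prior_spec}s on identical bin edges.
#' @param weights expert weights, non-negative, summing to 1 (default equal).
#' @return the pooled \code{\link{prior_histogram}}.
#' @export
pool_priors <- function(priors, weights = NULL) {
  stopifnot(is.list(priors), length(priors) >= 1L)
  if (!all(vapply(priors, function(p)
      is_prior_spec(p) && p$kind == "histogram", TRUE)))
    stop("all priors must be histogram priors", call. = FALSE)
  edges <- priors[[1L]]$edges
  same <- vapply(priors, function(p)
    length(p$edges) == length(edges) &&
      all(abs(p$edges - edges) < 1e-12), TRUE)
  if (!all(same))
    stop("invalid input: experts must share identical bin edges",
         call. = FALSE)
  k <- length(priors)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  pooled <- Reduce(`+`, Map(function(p, w) w * p$probs, priors, weights))
  prior_histogram(edges, pooled / sum(pooled))
}

#' Moment-match a normal prior to a histogram prior
#'
#' Bridges elicited histograms to the normal-prior path: location and scale
#' are the histogram's mean and SD computed from bin midpoints. A histogram
#' with all its mass in a single bin has zero midpoint-SD and is rejected:
#' use the histogram prior directly in that case.
#'
#' @param prior a histogram \code{prior_spec} with mass in >= 2 bins.
#' @return a \code{\link{prior_normal}}.
#' @export
fit_normal_to_histogram <- function(prior) {
  stopifnot(is_prior_spec(prior))
  if (prior$kind != "histogram")
    stop("expected a histogram prior", call. = FALSE)
  if (sum(prior$probs > 0) < 2L)
    stop(paste("histogram has zero spread (all mass in one bin);",
               "use the histogram prior directly"), call. = FALSE)
  prior_normal(prior_mean(prior), prior_sd(prior))
}

#' Read expert elicitation responses from CSV
#'
#' Expected columns: \code{expert}, \code{bin_lower}, \code{bin_upper},
#' \code{weight}; all experts must use the same grid.
#'
#' @param path CSV file path.
#' @return named list of histogram priors, one per expert.
#' @export
read_elicitation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert", "bin_lower", "bin_upper", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("elicitation file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$expert), function(d) {
    d <- d[order(d$bin_lower), ]
    if (!all(abs(d$bin_upper[-nrow(d)] - d$bin_lower[-1L]) < 1e-12))
      stop("bins must tile a contiguous grid", call. = FALSE)
    make_histogram_prior(c(d$bin_lower, d$bin_upper[nrow(d)]), d$weight)
  })
  out
}
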