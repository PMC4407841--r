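# Prior specifications for the mean treatment effect (IVR score units,
# positive = severity reduction under active treatment).

#' Scale of the proper normal used to represent a "flat" prior
#'
#' Non-informative priors are implemented as proper normals with this standard
#' deviation so every posterior computation stays proper. On the 1--9 IVR
#' severity scale a standard deviation of 100 is effectively flat.
#'
#' @export
FLAT_PRIOR_SD <- 100

#' Normal prior on the mean treatment effect
#'
#' @param location prior mean, in IVR score units.
#' @param scale prior standard deviation; must be strictly positive.
#' @return an object of class \code{prior_spec} with \code{kind = "normal"}.
#' @examples
#' prior_normal(1.75, 0.89)  # informative prior from the earlier crossover RCT
#' @export
prior_normal <- function(location, scale) {
  stopifnot(is.numeric(location), length(location) == 1L, is.finite(location),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("prior scale must be > 0", call. = FALSE)
  structure(list(kind = "normal", location = location, scale = scale),
            class = "prior_spec")
}

#' Non-informative ("flat") prior on the mean treatment effect
#'
#' A proper normal with location 0 and standard deviation
#' \code{\link{FLAT_PRIOR_SD}}.
#'
#' @return a \code{prior_spec} with \code{kind = "flat"}.
#' @export
prior_flat <- function() {
  structure(list(kind = "flat", location = 0, scale = FLAT_PRIOR_SD),
            class = "prior_spec")
}

#' Histogram prior on the mean treatment effect
#'
#' Piecewise-constant density over ordered bins, as produced by
#' histogram-based expert elicitation (see \code{\link{make_histogram_prior}}).
#'
#' @param edges strictly increasing bin edges (length \code{nbins + 1}).
#' @param probs per-bin probabilities, non-negative, summing to 1 within 1e-9.
#' @return a \code{prior_spec} with \code{kind = "histogram"}.
#' @export
prior_histogram <- function(edges, probs) {
  stopifnot(is.numeric(edges), is.numeric(probs))
  if (length(edges) != length(probs) + 1L)
    stop("need length(edges) == length(probs) + 1", call. = FALSE)
  if (any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (any(probs < 0)) stop("bin probabilities must be >= 0", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("bin probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(kind = "histogram", edges = as.numeric(edges),
                 probs = as.numeric(probs)),
            class = "prior_spec")
}

#' Degenerate point-mass prior
#'
#' Usable only as an assurance truth prior (a fixed true effect); rejected as
#' an analysis prior by the sampler.
#'
#' @param location the fixed value.
#' @return a \code{prior_spec} with \code{kind = "point"}.
#' @export
prior_point <- function(location) {
  stopifnot(is.numeric(location), length(location) == 1L, is.finite(location))
  structure(list(kind = "point", location = location), class = "prior_spec")
}

is_prior_spec <- function(x) inherits(x, "prior_spec")

#' @export
print.prior_spec <- function(x, ...) {
  switch(x$kind,
    normal = cat(sprintf("Normal prior: location %.4g, scale %.4g\n",
                         x$location, x$scale)),
    flat = cat(sprintf("Flat prior (proper normal, scale %g)\n", x$scale)),
    point = cat(sprintf("Point mass at %.4g\n", x$location)),
    histogram = cat(sprintf(
      "Histogram prior: %d bins on [%.4g, %.4g], mean %.4g\n",
      length(x$probs), x$edges[1L], x$edges[length(x$edges)], prior_mean(x))))
  invisible(x)
}

#' Mean of a prior specification
#' @param prior a \code{prior_spec}.
#' @return numeric mean.
#' @export
prior_mean <- function(prior) {
  stopifnot(is_prior_spec(prior))
  switch(prior$kind,
    normal = ,
    flat = ,
    point = prior$location,
    histogram = {
      mids <- (prior$edges[-1L] + prior$edges[-length(prior$edges)]) / 2
      sum(mids * prior$probs)
    })
}

#' Standard deviation of a prior specification
#' @param prior a \code{prior_spec}.
#' @return numeric standard deviation (0 for a point mass).
#' @export
prior_sd <- function(prior) {
  stopifnot(is_prior_spec(prior))
  switch(prior$kind,
    normal = ,
    flat = prior$scale,
    point = 0,
    histogram = {
      mids <- (prior$edges[-1L] + prior$edges[-length(prior$edges)]) / 2
      m <- sum(mids * prior$probs)
      sqrt(sum((mids - m)^2 * prior$probs))
    })
}

#' Draw random realizations from a prior
#'
#' Histogram draws are uniform within the sampled bin.
#'
#' @param prior a \code{prior_spec}.
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
prior_draw <- function(prior, n = 1L) {
  stopifnot(is_prior_spec(prior), n >= 1)
  switch(prior$kind,
    normal = ,
    flat = stats::rnorm(n, prior$location, prior$scale),
    point = rep(prior$location, n),
    histogram = {
      k <- sample.int(length(prior$probs), n, replace = TRUE,
                      prob = prior$probs)
      stats::runif(n, prior$edges[k], prior$edges[k + 1L])
    })
}

# Serialize / deserialize for JSON configs.
prior_to_list <- function(prior) unclass(prior)

prior_from_list <- function(x) {
  switch(x$kind,
    normal = prior_normal(x$location, x$scale),
    flat = prior_flat(),
    point = prior_point(x$location),
    histogram = prior_histogram(unlist(x$edges), unlist(x$probs)),
    stop("unknown prior kind: ", x$kind, call. = FALSE))
}
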