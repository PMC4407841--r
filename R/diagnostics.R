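# Convergence diagnostics: split-R-hat (potential scale reduction on
# half-chains) and effective sample size (via coda).

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classic between/within variance ratio
#' is computed over the resulting half-chains, so within-chain trends inflate
#' the statistic even for a single chain.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return the split R-hat; \code{NA} for degenerate (zero-variance) input.
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps * max(abs(means), 1))
    return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS pooled over chains.
ess_chains <- function(chains) {
  sum(vapply(chains, function(x) {
    if (stats::var(x) <= 0) return(length(x))
    as.numeric(coda::effectiveSize(coda::mcmc(x)))
  }, 0))
}

# Build the diagnostics table for a draws matrix split by chain.
diagnose_params <- function(mat, chain_id) {
  chains <- split(seq_len(nrow(mat)), chain_id)
  do.call(rbind, lapply(colnames(mat), function(p) {
    per_chain <- lapply(chains, function(idx) mat[idx, p])
    data.frame(param = p,
               rhat = split_rhat(per_chain),
               ess = ess_chains(per_chain),
               stringsAsFactors = FALSE)
  }))
}
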