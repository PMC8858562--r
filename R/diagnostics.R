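## Convergence diagnostics for the sampler output.

#' Split-half R-hat
#'
#' Potential scale reduction factor computed after splitting every chain in
#' half, so that within-chain trends register as apparent non-convergence
#' even with a single chain.
#'
#' @param x numeric matrix of draws, one column per chain (a vector is a
#'   single chain).
#' @return scalar R-hat; `NA` if the draws are (numerically) constant.
#' @export
split_rhat <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W <= 1e-14 * max(abs(means), 1)^2) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

## Effective sample size pooled over chains (coda's spectral estimator).
ess_pooled <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (sd(x) < 1e-14) return(NA_real_)
  sum(apply(x, 2, function(col) coda::effectiveSize(coda::as.mcmc(col))))
}

## Diagnostics table for the scalar summaries of a fit: one row per
## monitored quantity with split R-hat and ESS.
compute_diagnostics <- function(draws, chain_id) {
  chains <- sort(unique(chain_id))
  as_chain_mat <- function(v) {
    do.call(cbind, lapply(chains, function(ch) v[chain_id == ch]))
  }
  rows <- lapply(names(draws), function(nm) {
    v <- draws[[nm]]
    data.frame(parameter = nm,
               rhat = split_rhat(as_chain_mat(v)),
               ess = ess_pooled(as_chain_mat(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
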