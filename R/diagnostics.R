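## Convergence diagnostics: split-chain Rhat and effective sample size.

# draws: matrix with one column per chain (equal length).  Chains are split
# in half so within-chain drift is detected even with a single chain.
split_chains <- function(draws) {
  n <- nrow(draws)
  h <- floor(n / 2)
  do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(h), j], draws[n - h + seq_len(h), j])
  }))
}

#' Split-chain potential scale reduction factor
#'
#' @param draws Matrix of posterior draws, one column per chain.
#' @return The split-Rhat statistic (1 at perfect mixing); `NA` for a
#'   constant quantity.
#' @export
split_rhat <- function(draws) {
  draws <- split_chains(as.matrix(draws))
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  mns <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive
#' sequence, averaged over chains.
#'
#' @param draws Matrix of posterior draws, one column per chain.
#' @return Estimated effective sample size (capped at the number of draws).
#' @export
ess_draws <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  if (stats::sd(as.vector(draws)) < 1e-300) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    v <- stats::var(draws[, j])
    if (v <= 1e-300) return(rep(0, max_lag + 1))
    stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1)))
  rho[!is.finite(rho)] <- 0
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0
  prev <- Inf
  for (k in seq(1, max_lag, by = 2)) {
    pair <- rho[k] + if (k + 1 <= max_lag + 1) rho[k + 1] else 0
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
  }
  ess <- (n * m) / max(2 * tau - 1, 1e-12)
  min(ess, n * m)
}
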