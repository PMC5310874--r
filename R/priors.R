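#' Hyperprior configuration
#'
#' Configures the priors on the precision hyperparameters of the GMRF
#' effects and on the gender intercepts.  Two precision-prior families are
#' available: the penalised-complexity (PC) prior, induced by an
#' exponential prior on the standard deviation calibrated through
#' `P(sigma > u) = alpha`, and a uniform prior on the standard deviation,
#' bounded above by `sigma_max` so the posterior is proper regardless of
#' the data (a bounded stand-in for the fully improper uniform).
#'
#' @param family `"pc"` or `"uniform_sd"`, applied to every precision.
#' @param pc_u Threshold `u` on the standard-deviation scale (default 1).
#' @param pc_alpha Tail probability `alpha` in `P(sigma > u) = alpha`
#'   (default 0.01).
#' @param sigma_max Upper bound of the uniform-on-SD prior (default 100).
#' @param intercept_var Variance of the vague zero-mean normal prior on the
#'   gender intercepts `beta_g` (default 1000).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(family = c("pc", "uniform_sd"), pc_u = 1,
                         pc_alpha = 0.01, sigma_max = 100,
                         intercept_var = 1000) {
  family <- match.arg(family)
  if (!(pc_u > 0)) stop("pc_u must be positive", call. = FALSE)
  if (!(pc_alpha > 0 && pc_alpha < 1)) {
    stop("pc_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!(sigma_max > 0)) stop("sigma_max must be positive", call. = FALSE)
  if (!(intercept_var > 0)) stop("intercept_var must be positive", call. = FALSE)
  structure(list(family = family, pc_u = pc_u, pc_alpha = pc_alpha,
                 sigma_max = sigma_max, intercept_var = intercept_var),
            class = "prior_config")
}

#' Penalised-complexity prior log-density for a precision
#'
#' The PC prior for a precision `tau` is the type-2 Gumbel density
#' `pi(tau) = (lambda/2) tau^(-3/2) exp(-lambda tau^(-1/2))` with
#' `lambda = -log(alpha) / u`, i.e. the push-forward of an exponential
#' prior on the standard deviation `sigma = tau^(-1/2)` calibrated so that
#' `P(sigma > u) = alpha`.
#'
#' @param tau Precision (strictly positive; vectorised).
#' @param u Standard-deviation threshold.
#' @param alpha Tail probability.
#' @return Log-density values.
#' @export
pc_precision_logdensity <- function(tau, u = 1, alpha = 0.01) {
  if (any(!(tau > 0))) stop("tau must be strictly positive", call. = FALSE)
  if (!(u > 0) || !(alpha > 0 && alpha < 1)) {
    stop("need u > 0 and alpha in (0,1)", call. = FALSE)
  }
  lambda <- -log(alpha) / u
  log(lambda / 2) - 1.5 * log(tau) - lambda / sqrt(tau)
}

# Log-density (up to the family's own normalisation) of a precision under
# the configured prior; used by the samplers.
precision_logprior <- function(tau, priors) {
  if (priors$family == "pc") {
    pc_precision_logdensity(tau, priors$pc_u, priors$pc_alpha)
  } else {
    # sigma ~ U(0, sigma_max]: pi(tau) prop tau^(-3/2) on tau >= sigma_max^-2
    ifelse(tau >= priors$sigma_max^-2, -1.5 * log(tau), -Inf)
  }
}
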