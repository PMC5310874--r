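## Model comparison: Poisson deviance, DIC and WAIC, and model ranking.

#' Poisson deviance
#'
#' `D = 2 * sum(y * log(y / mu) - (y - mu))`, with the `y = 0` term read in
#' the limit as `2 * mu`.  Non-negative by the information inequality and
#' zero at the saturated fit `mu = y`.
#'
#' @param deaths Observed counts.
#' @param mu Fitted Poisson means; must be positive wherever `deaths > 0`.
#' @return The total deviance (a scalar).
#' @export
poisson_deviance <- function(deaths, mu) {
  y <- as.vector(deaths); mu <- as.vector(mu)
  if (length(y) != length(mu)) stop("length mismatch", call. = FALSE)
  if (any(mu <= 0 & y > 0)) {
    stop("domain error: zero fitted mean with positive count", call. = FALSE)
  }
  term <- ifelse(y > 0, y * log(y / mu) - (y - mu), mu)
  2 * sum(term)
}

# DIC from a vector of per-draw deviances and the plug-in deviance.
dic_from_deviances <- function(dev_draws, dev_hat) {
  dbar <- mean(dev_draws)
  p_dic <- dbar - dev_hat
  list(dic = dbar + p_dic, p_dic = p_dic, dev_bar = dbar, dev_hat = dev_hat)
}

# WAIC from a draws x cells matrix of pointwise log-densities.
waic_from_loglik <- function(lp) {
  if (any(!is.finite(lp))) {
    bad <- which(!is.finite(lp), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log-density at draw %d, cell %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  S <- nrow(lp)
  # lppd_i = log mean_s exp(lp_si), computed stably
  mx <- apply(lp, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(lp, 2, mx)))))
  p_waic <- sum(apply(lp, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

# Per-draw, per-cell Poisson log-density matrix for a fit.
pointwise_loglik <- function(fit, dataset) {
  lr <- posterior_lograte_draws(fit)
  off <- log(as.vector(dataset$population))
  y <- as.vector(dataset$deaths)
  lmu <- sweep(lr, 2, off, `+`)
  # dpois on the log scale: y*log(mu) - mu - log(y!)
  sweep(lmu, 2, y, `*`) - exp(lmu) - matrix(lgamma(y + 1), nrow(lmu),
                                            ncol(lmu), byrow = TRUE)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(mu_hat)`, where `Dbar` is the
#' posterior mean deviance and the plug-in deviance is evaluated at the
#' posterior means of the latent effects (the focus level at which the
#' log-linear predictor is specified).
#'
#' @param fit A [fit_gapc()] result.
#' @param dataset The [mortality_dataset()] the model was fitted to.
#' @return A `model_score` list with `dic`, `p_dic`, `waic`, `p_waic`
#'   fields (`waic` entries `NA`; see [waic()] and [model_score()]).
#' @export
dic <- function(fit, dataset) {
  lr <- posterior_lograte_draws(fit)
  off <- log(as.vector(dataset$population))
  y <- as.vector(dataset$deaths)
  mu_draws <- exp(sweep(lr, 2, off, `+`))
  dev_draws <- apply(mu_draws, 1, function(m) poisson_deviance(y, m))
  # plug-in at the posterior means of the effects (not of the rates)
  mean_fx <- lapply(fit$samples[setdiff(names(fit$samples), "tau")], colMeans)
  fit_hat <- fit
  for (e in names(mean_fx)) {
    fit_hat$samples[[e]] <- matrix(mean_fx[[e]], nrow = 1)
  }
  mu_hat <- exp(as.vector(posterior_lograte_draws(fit_hat)) + off)
  out <- dic_from_deviances(dev_draws, poisson_deviance(y, mu_hat))
  model_score(name = fit$spec$name, dic = out$dic, p_dic = out$p_dic)
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' `WAIC = -2 * (lppd - p_waic)` with the (g,a,i,t) cell as the pointwise
#' prediction unit: `lppd = sum_i log mean_s p(y_i | draw_s)` and
#' `p_waic = sum_i var_s log p(y_i | draw_s)`.
#'
#' @inheritParams dic
#' @return A `model_score` with `waic` and `p_waic` filled in.
#' @export
waic <- function(fit, dataset) {
  out <- waic_from_loglik(pointwise_loglik(fit, dataset))
  model_score(name = fit$spec$name, waic = out$waic, p_waic = out$p_waic,
              lppd = out$lppd)
}

#' Model comparison score
#'
#' @param name Model label.
#' @param dic,p_dic,waic,p_waic,lppd Criterion values (any may be `NA`).
#' @return An object of class `model_score`.
#' @export
model_score <- function(name, dic = NA_real_, p_dic = NA_real_,
                        waic = NA_real_, p_waic = NA_real_,
                        lppd = NA_real_) {
  structure(list(name = name, dic = dic, p_dic = p_dic, waic = waic,
                 p_waic = p_waic, lppd = lppd), class = "model_score")
}

#' Score a fitted model with both criteria
#'
#' @inheritParams dic
#' @return A `model_score` with both DIC and WAIC fields.
#' @export
score_model <- function(fit, dataset) {
  a <- dic(fit, dataset); b <- waic(fit, dataset)
  model_score(name = fit$spec$name, dic = a$dic, p_dic = a$p_dic,
              waic = b$waic, p_waic = b$p_waic, lppd = b$lppd)
}

#' Rank candidate models by an information criterion
#'
#' Orders models by ascending DIC or WAIC (smaller is better); ties are
#' broken by fewer effective parameters, then by model name.
#'
#' @param scores List of [model_score()] objects.
#' @param criterion `"waic"` or `"dic"`.
#' @return Data frame of the scores in ranked order with a `rank` column.
#' @export
rank_models <- function(scores, criterion = c("waic", "dic")) {
  criterion <- match.arg(criterion)
  if (!length(scores)) stop("no model scores supplied", call. = FALSE)
  if (inherits(scores, "model_score")) scores <- list(scores)
  tab <- do.call(rbind, lapply(scores, function(s)
    data.frame(name = s$name, dic = s$dic, p_dic = s$p_dic,
               waic = s$waic, p_waic = s$p_waic,
               stringsAsFactors = FALSE)))
  crit <- tab[[criterion]]
  pcol <- tab[[paste0("p_", criterion)]]
  o <- order(crit, pcol, tab$name)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
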