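## Posterior summaries, parameter naming, and on-disk result bundles.

# Human-readable scalar names for an effect sample matrix.
effect_par_names <- function(effect, dims) {
  switch(effect,
    beta = sprintf("beta[%d]", seq_len(dims$G)),
    alpha = as.vector(outer(seq_len(dims$T), seq_len(dims$G),
                            function(t, g) sprintf("alpha[%d,%d]", t, g))),
    gamma = as.vector(outer(seq_len(dims$I), seq_len(dims$G),
                            function(i, g) sprintf("gamma[%d,%d]", i, g))),
    kappa = as.vector(outer(seq_len(dims$K), seq_len(dims$G),
                            function(k, g) sprintf("kappa[%d,%d]", k, g))),
    phi = sprintf("phi[%d]", seq_len(dims$A)),
    delta = as.vector(t(outer(seq_len(dims$A), seq_len(dims$T),
                              function(a, t) sprintf("delta[%d,%d]", a, t))))
  )
}

# Posterior summary table (median, mean, sd, central 95% interval) plus
# split-Rhat and ESS for every scalar in the fit.
summarize_draws <- function(fit) {
  rows <- list()
  for (e in names(fit$samples)) {
    mat <- fit$samples[[e]]
    nms <- if (e == "tau") paste0("tau_", colnames(mat)) else
      effect_par_names(e, fit$dims)
    for (j in seq_len(ncol(mat))) {
      v <- mat[, j]
      per_chain <- matrix(v, nrow = fit$keep, ncol = fit$chains)
      q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nms[j], effect = e, index = j,
        median = q[2], mean = mean(v), sd = stats::sd(v),
        q2.5 = q[1], q97.5 = q[3],
        ess = ess_draws(per_chain), rhat = split_rhat(per_chain),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.gapc_fit <- function(object, ...) object$summary

# Extract an effect's draws as a draws x length matrix.
effect_draws <- function(fit, effect) {
  m <- fit$samples[[effect]]
  if (is.null(m)) {
    stop(sprintf("structural error: effect '%s' is not in the fitted model",
                 effect), call. = FALSE)
  }
  m
}

# Draws of the cell log-rates: draws x ncells matrix, cells flattened in
# storage order (g fastest).  Assembled from the stored effect draws, so
# any summary recomputed from a saved bundle is bit-identical.
posterior_lograte_draws <- function(fit) {
  d <- fit$dims
  idx <- cell_index_table(d)
  S <- nrow(fit$samples$beta)
  eta <- fit$samples$beta[, idx$g, drop = FALSE]
  if (!is.null(fit$samples$alpha)) {
    eta <- eta + fit$samples$alpha[, (idx$g - 1L) * d$T + idx$t, drop = FALSE]
  }
  if (!is.null(fit$samples$gamma)) {
    eta <- eta + fit$samples$gamma[, (idx$g - 1L) * d$I + idx$i, drop = FALSE]
  }
  if (!is.null(fit$samples$kappa)) {
    eta <- eta + fit$samples$kappa[, (idx$g - 1L) * d$K + idx$k, drop = FALSE]
  }
  if (!is.null(fit$samples$phi)) {
    eta <- eta + fit$samples$phi[, idx$a, drop = FALSE]
  }
  if (!is.null(fit$samples$delta)) {
    eta <- eta + fit$samples$delta[, (idx$a - 1L) * d$T + idx$t, drop = FALSE]
  }
  eta
}

# Posterior-median cell rates as a G x A x I x T array.
posterior_median_rates <- function(fit) {
  lr <- posterior_lograte_draws(fit)
  d <- fit$dims
  array(exp(apply(lr, 2, stats::median)), dim = c(d$G, d$A, d$I, d$T))
}

#' Write a fitted model to an on-disk bundle
#'
#' Writes a directory holding the posterior summary as delimited text, the
#' model specification as YAML, the raw sample arrays, and a JSON manifest
#' recording the seed, chain configuration, a hash of the specification and
#' the package version — enough to recompute every summary bit-identically.
#'
#' @param fit A [fit_gapc()] result.
#' @param dir Output directory (created if needed).
#' @export
write_posterior <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_model_spec(fit$spec, file.path(dir, "spec.yaml"))
  saveRDS(fit$samples, file.path(dir, "samples.rds"))
  saveRDS(fit[c("chain_id", "keep", "chains", "iterations", "warmup",
                "labels", "accept")],
          file.path(dir, "meta.rds"))
  manifest <- list(
    kind = "gapc_posterior_bundle",
    seed = fit$seed, chains = fit$chains, iterations = fit$iterations,
    warmup = fit$warmup,
    spec_hash = unname(tools::md5sum(file.path(dir, "spec.yaml"))),
    package_version = as.character(utils::packageVersion("gapcmap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a fitted-model bundle written by [write_posterior()]
#'
#' @param dir Bundle directory.
#' @return A `gapc_fit` object equivalent to the one written.
#' @export
read_posterior <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  spec <- read_model_spec(file.path(dir, "spec.yaml"))
  meta <- readRDS(file.path(dir, "meta.rds"))
  fit <- structure(c(
    list(samples = readRDS(file.path(dir, "samples.rds"))),
    meta,
    list(seed = manifest$seed, spec = spec, dims = spec$dims)
  ), class = "gapc_fit")
  fit$summary <- summarize_draws(fit)
  fit
}
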