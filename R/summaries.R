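## Posterior summaries of a fitted model: average rate profiles by age,
## cohort and period; spatial effects with exceedance probabilities;
## space-time risk surfaces; region-to-national cohort rate ratios; and
## age-specific rate trajectories.  Every summary is a deterministic
## function of the stored draws.

# Population-weighted (or unweighted) mean of posterior-median cell rates
# over the cells at each level of `axis`, for one gender.
profile_from_rates <- function(rhat, dataset, axis, gender, weighted = TRUE,
                               areas = NULL) {
  d <- dataset$dims
  idx <- cell_index_table(d)
  sel <- idx$g == gender
  if (!is.null(areas)) sel <- sel & idx$a %in% areas
  lev <- switch(axis, age = idx$i, cohort = idx$k, period = idx$t,
                stop("axis must be age, cohort or period", call. = FALSE))
  nlev <- switch(axis, age = d$I, cohort = d$K, period = d$T)
  r <- as.vector(rhat)[sel]
  n <- as.vector(dataset$population)[sel]
  lv <- lev[sel]
  w <- if (weighted) n else rep(1, length(n))
  num <- grp_sum(w * r, lv, nlev)
  den <- grp_sum(w, lv, nlev)
  rate <- ifelse(den > 0, num / den * 1e5, NA_real_)
  data.frame(level = seq_len(nlev), rate = rate, weight = den)
}

#' Posterior average rate profile by age, cohort or period
#'
#' For each level of the chosen axis, the population-weighted mean of the
#' posterior-median cell rates over all cells at that level, per 100,000.
#' With `weighted = TRUE` (default) the national profile equals total
#' expected deaths over total person-time at each level; `weighted = FALSE`
#' gives the unweighted mean of cell rates.  Cohort levels group cells
#' through the index `k = M * (I - i) + t`.  Levels with zero population
#' (possible for cohort levels when `T < M`) are returned as `NA` and
#' flagged.
#'
#' @param fit A [fit_gapc()] result.
#' @param dataset The fitted [mortality_dataset()].
#' @param axis `"age"`, `"cohort"` or `"period"`.
#' @param gender Gender index in `1..G`.
#' @param weighted Population-weight the average (default) or not.
#' @return Data frame with columns `level`, `label`, `rate` (per 100,000),
#'   `weight`; an attribute `excluded_levels` lists zero-population levels.
#' @export
average_rate_profile <- function(fit, dataset, axis = c("age", "cohort", "period"),
                                 gender = 1L, weighted = TRUE) {
  axis <- match.arg(axis)
  rhat <- posterior_median_rates(fit)
  out <- profile_from_rates(rhat, dataset, axis, gender, weighted)
  out$label <- switch(axis,
    age = dataset$labels$age_group,
    period = dataset$labels$year,
    cohort = as.character(out$level))
  excl <- out$level[is.na(out$rate)]
  attr(out, "excluded_levels") <- excl
  out[c("level", "label", "rate", "weight")]
}

#' Region-specific spatial effects and exceedance probabilities
#'
#' Posterior medians of `exp(phi_a)` together with the posterior
#' probability `P(exp(phi_a) > 1)` for every area.  Because `exp` is
#' monotone, the median of `exp(phi)` equals `exp(median(phi))`, and the
#' exceedance equals `P(phi_a > 0)`.
#'
#' @param fit A [fit_gapc()] result containing the spatial effect.
#' @return Data frame with columns `area`, `label`, `effect`
#'   (median of `exp(phi)`), `prob_gt_1`.
#' @export
region_effect_map <- function(fit) {
  phi <- effect_draws(fit, "phi")
  data.frame(
    area = seq_len(ncol(phi)),
    label = fit$labels$area,
    effect = exp(apply(phi, 2, stats::median)),
    prob_gt_1 = apply(exp(phi), 2, exceedance_probability, threshold = 1)
  )
}

#' Space-time risk surface
#'
#' Per-(area, period) posterior median of `exp(phi_a + delta_at)`, computed
#' draw-wise before taking the median.  With `delta` identically zero the
#' surface is constant over time and equals the [region_effect_map()]
#' medians.
#'
#' @param fit A [fit_gapc()] result containing `phi` and `delta`.
#' @return An `A x T` matrix of posterior medians with area labels as
#'   row names.
#' @export
spacetime_surface <- function(fit) {
  phi <- effect_draws(fit, "phi")
  del <- effect_draws(fit, "delta")
  d <- fit$dims
  out <- matrix(NA_real_, d$A, d$T,
                dimnames = list(fit$labels$area, fit$labels$year))
  for (a in seq_len(d$A)) {
    cols <- (a - 1L) * d$T + seq_len(d$T)
    out[a, ] <- apply(exp(phi[, a] + del[, cols, drop = FALSE]), 2,
                      stats::median)
  }
  out
}

#' Region-to-national cohort rate ratios
#'
#' Divides each region's average cohort rate profile (the
#' [average_rate_profile()] restricted to the area) cohort-wise by the
#' national cohort profile.  Cohorts with no national population are
#' excluded (`NA`).
#'
#' @param fit A [fit_gapc()] result.
#' @param dataset The fitted [mortality_dataset()].
#' @param gender Gender index.
#' @param weighted Population-weight the averages (default `TRUE`).
#' @return A `K x A` matrix of ratios (cohorts in rows, areas in columns).
#' @export
cohort_ratio_map <- function(fit, dataset, gender = 1L, weighted = TRUE) {
  rhat <- posterior_median_rates(fit)
  d <- dataset$dims
  national <- profile_from_rates(rhat, dataset, "cohort", gender, weighted)$rate
  out <- matrix(NA_real_, d$K, d$A,
                dimnames = list(NULL, dataset$labels$area))
  for (a in seq_len(d$A)) {
    reg <- profile_from_rates(rhat, dataset, "cohort", gender, weighted,
                              areas = a)$rate
    out[, a] <- ifelse(!is.na(national) & national > 0, reg / national,
                       NA_real_)
  }
  out
}

#' Age-specific rate trajectories by cohort or period
#'
#' For each age group, the national (population-weighted across areas)
#' posterior-median rate trajectory, indexed either by period `t` or by the
#' cohorts that age group passes through (`k = M * (I - i) + t`, a span of
#' exactly `T` consecutive cohort indices; the oldest group covers
#' `k = 1..T`).
#'
#' @param fit A [fit_gapc()] result.
#' @param dataset The fitted [mortality_dataset()].
#' @param axis `"cohort"` or `"period"`.
#' @param gender Gender index.
#' @return Data frame with columns `age_group` (index), `age_label`,
#'   `level` (cohort or period index), `rate` (per 100,000).
#' @export
age_profiles_by <- function(fit, dataset, axis = c("cohort", "period"),
                            gender = 1L) {
  axis <- match.arg(axis)
  rhat <- posterior_median_rates(fit)
  d <- dataset$dims
  idx <- cell_index_table(d)
  rows <- list()
  for (i in seq_len(d$I)) {
    for (t in seq_len(d$T)) {
      sel <- idx$g == gender & idx$i == i & idx$t == t
      n <- as.vector(dataset$population)[sel]
      r <- as.vector(rhat)[sel]
      lev <- if (axis == "period") t else cohort_index(i, t, d)
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = i, age_label = dataset$labels$age_group[i],
        level = lev, rate = sum(n * r) / sum(n) * 1e5
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full summary bundle of a fitted model
#'
#' Convenience wrapper computing every reported posterior summary: rate
#' profiles by age, cohort and period per gender, the region effect map,
#' the space-time surface, cohort ratios per gender, and age-specific
#' trajectories.
#'
#' @param fit A [fit_gapc()] result.
#' @param dataset The fitted [mortality_dataset()].
#' @param weighted Population-weight marginal averages (default `TRUE`).
#' @return A list of class `summary_bundle`.
#' @export
summary_bundle <- function(fit, dataset, weighted = TRUE) {
  d <- fit$dims
  prof <- function(axis) lapply(seq_len(d$G), function(g)
    average_rate_profile(fit, dataset, axis, g, weighted))
  out <- list(
    avg_rate_by_age = prof("age"),
    avg_rate_by_cohort = prof("cohort"),
    avg_rate_by_period = prof("period"),
    region_effects = if (!is.null(fit$samples$phi)) region_effect_map(fit),
    spacetime = if (!is.null(fit$samples$phi) && !is.null(fit$samples$delta))
      spacetime_surface(fit),
    cohort_ratios = lapply(seq_len(d$G), function(g)
      cohort_ratio_map(fit, dataset, g, weighted)),
    age_profiles_cohort = lapply(seq_len(d$G), function(g)
      age_profiles_by(fit, dataset, "cohort", g)),
    age_profiles_period = lapply(seq_len(d$G), function(g)
      age_profiles_by(fit, dataset, "period", g))
  )
  structure(out, class = "summary_bundle")
}

#' Plot rate profiles on a semi-logarithmic scale
#'
#' Draws per-gender rate profiles (age, cohort or period on the x axis,
#' rate per 100,000 on a log y axis), the presentation convention for
#' age-period-cohort mortality summaries.
#'
#' @param profiles List of per-gender profile data frames from
#'   [average_rate_profile()].
#' @param gender_labels Labels for the legend.
#' @param xlab X-axis label.
#' @param main Plot title.
#' @export
plot_rate_profiles <- function(profiles, gender_labels = NULL,
                               xlab = "level", main = "") {
  stopifnot(length(profiles) >= 1)
  xs <- profiles[[1]]$level
  ys <- vapply(profiles, function(p) p$rate, numeric(length(xs)))
  ys <- pmax(as.matrix(ys), 1e-6)
  graphics::matplot(xs, ys, type = "l", lty = seq_along(profiles),
                    col = seq_along(profiles), log = "y", xlab = xlab,
                    ylab = "rate per 100,000", main = main)
  if (!is.null(gender_labels)) {
    graphics::legend("topleft", legend = gender_labels,
                     lty = seq_along(profiles), col = seq_along(profiles),
                     bty = "n")
  }
  invisible(NULL)
}
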