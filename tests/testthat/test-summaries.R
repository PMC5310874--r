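# Posterior summaries: rate profiles, spatial effects, surfaces, ratios.

# A deterministic fake posterior on a tiny grid with hand-computable medians.
toy_summary_fit <- function() {
  d <- study_dims(1, 2, 2, 2, M = 1)   # K = 3
  set.seed(5)
  S <- 201
  draws <- list(
    beta = matrix(rnorm(S, log(1e-4), 0.05), S, 1),
    phi = cbind(rnorm(S, 0.2, 0.1), rnorm(S, -0.2, 0.1)),
    delta = matrix(rnorm(S * 4, 0, 0.05), S, 4)
  )
  d2 <- d
  fit <- fake_fit(draws, d2)
  pop <- array(c(1e4, 3e4, 2e4, 4e4, 1.5e4, 2.5e4, 3.5e4, 4.5e4),
               dim = c(1, 2, 2, 2))
  ds <- mortality_dataset(array(0L, dim(pop)), pop,
                          labels = fit$labels, M = 1)
  list(fit = fit, ds = ds, d = d)
}

test_that("average rate profiles are population-weighted means of median rates", {
  ts <- toy_summary_fit()
  rhat <- gapcmap:::posterior_median_rates(ts$fit)
  prof <- average_rate_profile(ts$fit, ts$ds, "age", gender = 1)
  # hand-computed weighted mean for each age level
  pop <- ts$ds$population
  for (i in 1:2) {
    num <- sum(rhat[1, , i, ] * pop[1, , i, ])
    expect_equal(prof$rate[i], num / sum(pop[1, , i, ]) * 1e5)
  }
  # unweighted alternative
  prof_u <- average_rate_profile(ts$fit, ts$ds, "age", gender = 1,
                                 weighted = FALSE)
  expect_equal(prof_u$rate[1], mean(rhat[1, , 1, ]) * 1e5)

  # single-area, single-period data: the age profile is the per-age medians
  d1 <- study_dims(1, 1, 3, 1, M = 1)
  S <- 101
  dr <- list(beta = matrix(log(1e-4), S, 1),
             gamma = matrix(rnorm(S * 3, rep(c(-0.5, 0, 0.5), each = S), 0.1),
                            S, 3))
  f1 <- fake_fit(dr, d1)
  ds1 <- mortality_dataset(array(0L, c(1, 1, 3, 1)),
                           array(1e4, c(1, 1, 3, 1)), labels = f1$labels,
                           M = 1)
  p1 <- average_rate_profile(f1, ds1, "age", 1)
  med <- exp(log(1e-4) + apply(dr$gamma, 2, median)) * 1e5
  expect_equal(p1$rate, med)
})

test_that("region effect maps use exp-scale medians and exceedance", {
  d <- study_dims(1, 3, 2, 2, M = 1)
  S <- 400
  set.seed(2)
  phi <- cbind(rep(0, S), rnorm(S, 0, 0.1), rnorm(S, 0.5, 0.1))
  fit <- fake_fit(list(beta = matrix(-9, S, 1), phi = phi), d)
  rem <- region_effect_map(fit)
  expect_equal(rem$effect[1], 1)          # all-zero draws
  expect_equal(rem$prob_gt_1[1], 0)       # strictly greater than 1
  # median(exp(x)) = exp(median(x))
  expect_equal(rem$effect, exp(apply(phi, 2, median)))
  # symmetric draws around zero: probability about one half
  expect_equal(rem$prob_gt_1[2], 0.5, tolerance = 0.1)
  expect_gt(rem$prob_gt_1[3], 0.99)
})

test_that("space-time surfaces are draw-wise medians of exp(phi + delta)", {
  ts <- toy_summary_fit()
  fit <- ts$fit
  surf <- spacetime_surface(fit)
  # brute-force per-cell oracle
  for (a in 1:2) for (t in 1:2) {
    dr <- exp(fit$samples$phi[, a] + fit$samples$delta[, (a - 1) * 2 + t])
    expect_equal(surf[a, t], median(dr))
  }
  # delta == 0: constant over time and equal to the region map
  fit0 <- fit
  fit0$samples$delta <- matrix(0, nrow(fit$samples$phi), 4)
  surf0 <- spacetime_surface(fit0)
  expect_equal(surf0[, 1], surf0[, 2])
  expect_equal(unname(surf0[, 1]), region_effect_map(fit0)$effect)
  # adding a constant c to all delta draws multiplies the surface by e^c
  fitc <- fit
  fitc$samples$delta <- fit$samples$delta + 0.3
  expect_equal(spacetime_surface(fitc), surf * exp(0.3))
})

test_that("cohort ratios divide regional by national profiles", {
  ts <- toy_summary_fit()
  # single-area study: every ratio is 1
  d1 <- study_dims(1, 1, 2, 2, M = 1)
  S <- 101
  f1 <- fake_fit(list(beta = matrix(-9, S, 1),
                      kappa = matrix(rnorm(S * 3, 0, 0.1), S, 3)), d1)
  ds1 <- mortality_dataset(array(0L, c(1, 1, 2, 2)),
                           array(1e4, c(1, 1, 2, 2)), labels = f1$labels,
                           M = 1)
  cr1 <- cohort_ratio_map(f1, ds1, 1)
  expect_equal(as.vector(cr1[!is.na(cr1)]), rep(1, sum(!is.na(cr1))))

  # an area with rates exactly double the other: ratios follow arithmetic
  cr <- cohort_ratio_map(ts$fit, ts$ds, 1)
  rhat <- gapcmap:::posterior_median_rates(ts$fit)
  pop <- ts$ds$population
  idx <- gapcmap:::cell_index_table(ts$d)
  for (k in 1:3) {
    sel <- idx$k == k
    nat <- sum(as.vector(rhat)[sel] * as.vector(pop)[sel]) /
      sum(as.vector(pop)[sel])
    sel1 <- sel & idx$a == 1
    reg <- sum(as.vector(rhat)[sel1] * as.vector(pop)[sel1]) /
      sum(as.vector(pop)[sel1])
    expect_equal(unname(cr[k, 1]), reg / nat)
  }
})

test_that("age trajectories cover exactly T consecutive cohorts per age group", {
  d <- study_dims(1, 1, 3, 4, M = 2)   # K = 8
  S <- 51
  f <- fake_fit(list(beta = matrix(log(1e-4), S, 1)), d)
  ds <- mortality_dataset(array(0L, c(1, 1, 3, 4)),
                          array(1e4, c(1, 1, 3, 4)), labels = f$labels,
                          M = 2)
  tr <- age_profiles_by(f, ds, "cohort", 1)
  for (i in 1:3) {
    lev <- sort(tr$level[tr$age_group == i])
    expect_equal(lev, d$M * (d$I - i) + 1:4)  # T consecutive cohort indices
  }
  # oldest age group spans cohorts 1..T
  expect_equal(sort(tr$level[tr$age_group == 3]), 1:4)
  # single-cell trajectory equals the cell's median rate
  expect_equal(unique(tr$rate), 1e-4 * 1e5)
})

test_that("summaries recomputed from a saved bundle are bit-identical", {
  bb <- benchmark_fit()
  fit <- bb$fit; ds <- bb$sim$dataset
  dir <- file.path(withr::local_tempdir(), "bundle")
  write_posterior(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  fit2 <- read_posterior(dir)
  expect_identical(fit2$samples, fit$samples)
  expect_identical(summary_bundle(fit2, ds), summary_bundle(fit, ds))
  expect_identical(region_effect_map(fit2), region_effect_map(fit))
})
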