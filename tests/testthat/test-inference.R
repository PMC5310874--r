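# Priors, the MCMC sampler and its small-scale oracles.

test_that("the PC precision prior has the stated closed form and normalises", {
  u <- 1; alpha <- 0.01
  lambda <- -log(alpha) / u
  expect_equal(lambda, 4.60517, tolerance = 1e-5)
  expect_equal(pc_precision_logdensity(1, u, alpha), log(lambda / 2) - lambda)
  # density integrates to 1 over (0, Inf)
  int <- stats::integrate(function(t) exp(pc_precision_logdensity(t, u, alpha)),
                          0, Inf, rel.tol = 1e-8)
  expect_equal(int$value, 1, tolerance = 1e-6)
  # and for other calibrations
  int2 <- stats::integrate(function(t) exp(pc_precision_logdensity(t, 0.3, 0.1)),
                           0, Inf, rel.tol = 1e-8)
  expect_equal(int2$value, 1, tolerance = 1e-6)
  expect_error(pc_precision_logdensity(0), "positive")
  expect_error(pc_precision_logdensity(1, u = -1), "u > 0")
})

test_that("exceedance probabilities count draws above the threshold", {
  expect_equal(exceedance_probability(c(2, 3, 0.5), 1), 2 / 3)
  expect_equal(exceedance_probability(c(2, 3), 1), 1)
  expect_error(exceedance_probability(numeric(0), 1), "no draws")
  # monotone transform: P(exp(x) > 1) = P(x > 0)
  set.seed(1)
  x <- rnorm(500)
  expect_equal(exceedance_probability(exp(x), 1), exceedance_probability(x, 0))
})

# Small datasets used by the sampler oracles ------------------------------

intercept_dataset <- function() {
  deaths <- array(c(3, 2, 4, 1), dim = c(1, 1, 2, 2))
  population <- array(25000, dim = c(1, 1, 2, 2))
  mortality_dataset(deaths, population,
                    labels = list(gender = "f", area = "a",
                                  age_group = c("[25,30)", "[30,35)"),
                                  year = c("1990", "1991")))
}

test_that("an intercept-only posterior matches a 1-D grid oracle", {
  ds <- intercept_dataset()
  spec <- model_spec(ds$dims, effects = "beta", interaction_type = "none")
  fit <- fit_gapc(ds, NULL, spec, chains = 2, iterations = 2500,
                  warmup = 1000, seed = 5)
  sm <- fit$summary[fit$summary$parameter == "beta[1]", ]

  # grid oracle: total deaths 10, person-time 1e5, N(0, 1000) prior
  bg <- seq(-13, -6, length.out = 40001)
  lp <- bg * 10 - 1e5 * exp(bg) - bg^2 / 2000
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_mean <- sum(w * bg)
  oracle_sd <- sqrt(sum(w * bg^2) - oracle_mean^2)
  mcse <- sm$sd / sqrt(sm$ess)
  expect_lt(abs(sm$mean - oracle_mean), 2 * mcse)
  expect_equal(sm$sd, oracle_sd, tolerance = 0.1)
})

test_that("a period-effect toy model matches an importance-sampling oracle", {
  # 1 gender, 1 area, intercept + RW1 period effect over T = 5, precision
  # fixed: 6 latent scalars (beta, alpha_1..5 with one sum constraint)
  set.seed(3)
  deaths <- array(rpois(10, 8), dim = c(1, 1, 2, 5))
  population <- array(5e4, dim = c(1, 1, 2, 5))
  ds <- mortality_dataset(deaths, population,
                          labels = list(gender = "f", area = "a",
                                        age_group = c("[25,30)", "[30,35)"),
                                        year = as.character(1990:1994)))
  tau_a <- 25
  spec <- model_spec(ds$dims, effects = c("beta", "alpha"),
                     interaction_type = "none")
  fit <- fit_gapc(ds, NULL, spec, chains = 2, iterations = 2500,
                  warmup = 1000, seed = 11, fixed_tau = list(alpha = tau_a))

  # oracle: Laplace approximation at the mode of (beta, z) with alpha = Z z,
  # corrected by importance sampling
  Tn <- 5
  Ctr <- matrix(1, 1, Tn)
  Zo <- svd(Ctr, nu = 0, nv = Tn)$v[, 2:Tn]        # sum-to-zero basis
  Q <- as.matrix(rw_precision(Tn, 1)$matrix)
  y_t <- apply(deaths, 4, sum)
  n_t <- apply(population, 4, sum)
  lpost <- function(th) {
    beta <- th[1]; a <- as.vector(Zo %*% th[-1])
    eta <- beta + a
    sum(y_t * eta - n_t * exp(eta)) - beta^2 / 2000 -
      0.5 * tau_a * sum(a * (Q %*% a))
  }
  opt <- optim(c(log(sum(y_t) / sum(n_t)), rep(0, 4)), function(th) -lpost(th),
               method = "BFGS", hessian = TRUE)
  H <- opt$hessian
  Rh <- chol(solve(H))
  set.seed(99)
  S <- 40000
  zs <- matrix(rnorm(S * 5), S, 5) %*% Rh
  ths <- sweep(zs, 2, opt$par, `+`)
  lq <- -0.5 * rowSums((zs %*% H) * zs)  # log N(th; mode, H^-1) up to const
  lt <- apply(ths, 1, lpost)
  wgt <- exp(lt - lq - max(lt - lq)); wgt <- wgt / sum(wgt)
  oracle_beta <- sum(wgt * ths[, 1])
  alpha_draws <- ths[, -1] %*% t(Zo)      # S x 5 draws of alpha
  oracle_alpha <- as.vector(crossprod(alpha_draws, wgt))

  sm <- fit$summary
  for (j in 1:5) {
    row <- sm[sm$parameter == sprintf("alpha[%d,1]", j), ]
    mcse <- row$sd / sqrt(row$ess)
    expect_lt(abs(row$mean - oracle_alpha[j]), 3 * mcse)
  }
  brow <- sm[sm$parameter == "beta[1]", ]
  expect_lt(abs(brow$mean - oracle_beta), 3 * brow$sd / sqrt(brow$ess))
})

test_that("identical seeds reproduce a fit bit for bit", {
  ds <- intercept_dataset()
  spec <- model_spec(ds$dims, effects = c("beta", "alpha"),
                     interaction_type = "none")
  f1 <- fit_gapc(ds, NULL, spec, chains = 2, iterations = 200, warmup = 100,
                 seed = 42)
  f2 <- fit_gapc(ds, NULL, spec, chains = 2, iterations = 200, warmup = 100,
                 seed = 42)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$summary, f2$summary)
  f3 <- fit_gapc(ds, NULL, spec, chains = 2, iterations = 200, warmup = 100,
                 seed = 43)
  expect_false(identical(f1$samples$beta, f3$samples$beta))
})

test_that("every retained draw satisfies the constraint system", {
  bb <- benchmark_fit()
  fit <- bb$fit
  d <- fit$dims
  viol <- c(
    alpha = max(abs(cbind(
      rowSums(fit$samples$alpha[, 1:d$T]),
      rowSums(fit$samples$alpha[, d$T + 1:d$T])))),
    gamma = max(abs(cbind(
      rowSums(fit$samples$gamma[, 1:d$I]),
      rowSums(fit$samples$gamma[, d$I + 1:d$I])))),
    kappa = max(abs(cbind(
      rowSums(fit$samples$kappa[, 1:d$K]),
      rowSums(fit$samples$kappa[, d$K + 1:d$K])))),
    phi = max(abs(rowSums(fit$samples$phi))),
    delta = max(abs(rowSums(fit$samples$delta)))  # type I: global sum
  )
  expect_lt(max(viol), 1e-8)
})

test_that("the benchmark fit mixes adequately and recovers the truth", {
  bb <- benchmark_fit()
  sm <- bb$fit$summary
  eff <- sm[sm$effect != "tau", ]
  expect_gt(min(eff$ess, na.rm = TRUE), 100)
  expect_lt(max(eff$rhat, na.rm = TRUE), 1.1)
  # true gender intercepts inside the central 95% intervals
  btrue <- bb$sim$truth$effects$beta
  brow <- sm[sm$effect == "beta", ]
  expect_true(all(btrue >= brow$q2.5 & btrue <= brow$q97.5))
  # the simulated north-south spatial gradient is recovered
  phi_true <- bb$sim$truth$effects$phi
  rem <- region_effect_map(bb$fit)
  expect_gt(cor(log(rem$effect), phi_true), 0.9)
})

test_that("relabelling areas together with the graph relabels the posterior", {
  d <- study_dims(2, 9, 3, 4)
  g <- lattice_graph(3, 3)
  spec <- model_spec(d, effects = c("beta", "gamma", "phi"),
                     interaction_type = "none")
  truth <- gapc_truth(spec, g, phi_sd = 0.3, seed = 8)
  sim <- simulate_gapc_dataset(spec, g, truth = truth, pop_scale = 1e5,
                               seed = 21)
  perm <- c(4, 1, 7, 3, 9, 2, 6, 8, 5)   # new index of each old area
  ds2 <- sim$dataset
  ds2$deaths[, perm, , ] <- sim$dataset$deaths
  ds2$population[, perm, , ] <- sim$dataset$population
  ds2$labels$area[perm] <- sim$dataset$labels$area
  g2 <- adjacency_graph(9, cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                        labels = ds2$labels$area)
  f1 <- fit_gapc(sim$dataset, g, spec, chains = 1, iterations = 900,
                 warmup = 300, seed = 5)
  f2 <- fit_gapc(ds2, g2, spec, chains = 1, iterations = 900,
                 warmup = 300, seed = 6)
  m1 <- colMeans(f1$samples$phi)
  m2 <- colMeans(f2$samples$phi)
  expect_equal(m2[perm], m1, tolerance = 0.03, ignore_attr = TRUE)
  expect_gt(cor(m2[perm], m1), 0.99)
})
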