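# GMRF structure matrices, cohort indexing, constraints, linear predictor.

test_that("cohort index follows k = M(I-i) + t and its diagonal geometry", {
  d <- study_dims(2, 50, 13, 24, M = 5)
  expect_equal(cohort_index(13, 1, d), 1)    # oldest age, first period
  expect_equal(cohort_index(1, 24, d), 84)   # youngest age, last period = K
  expect_equal(cohort_index(7, 10, d), 40)   # 5*6 + 10
  expect_error(cohort_index(0, 1, d), "out of range")
  expect_error(cohort_index(1, 25, d), "out of range")

  # cells sharing a cohort differ by dt = M * di exactly
  idx <- expand.grid(i = 1:13, t = 1:24)
  idx$k <- cohort_index(idx$i, idx$t, d)
  for (k in sample(unique(idx$k), 10)) {
    cells <- idx[idx$k == k, ]
    if (nrow(cells) > 1) {
      dd <- cells[order(cells$i), ]
      expect_equal(diff(dd$t), d$M * diff(dd$i))
    }
  }
})

test_that("random-walk precisions have the stated rank and kernel", {
  Q1 <- rw_precision(3, 1)
  expect_equal(as.matrix(Q1$matrix),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(Q1$rank, 2)
  expect_equal(as.matrix(rw_precision(2, 1)$matrix),
               matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)

  Q2 <- rw_precision(5, 2)
  expect_equal(Q2$rank, 3)
  # kernel contains constants and the linear trend
  expect_lt(max(abs(Q2$matrix %*% rep(1, 5))), 1e-10)
  expect_lt(max(abs(Q2$matrix %*% (1:5))), 1e-10)
  # and the claimed orthonormal kernel basis is annihilated
  expect_lt(max(abs(Q2$matrix %*% Q2$null_space_basis)), 1e-10)
  expect_error(rw_precision(2, 2), "n > order")

  # rank n - d and polynomial annihilation across sizes and orders
  for (n in c(4, 9, 24)) for (ord in 1:2) {
    Q <- rw_precision(n, ord)
    expect_equal(Q$rank, n - ord)
    expect_equal(Q$rank + ncol(Q$null_space_basis), n)
    for (p in seq_len(ord) - 1) {
      expect_lt(max(abs(Q$matrix %*% (seq_len(n)^p))), 1e-8)
    }
  }
})

test_that("the ICAR precision is the graph Laplacian with kernel per component", {
  g3 <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
  Q <- icar_precision(g3)
  expect_equal(as.matrix(Q$matrix),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(Q$rank, 2)
  expect_lt(max(abs(Matrix::rowSums(Q$matrix))), 1e-12)

  # isolated node: zero row/column, kernel dimension >= 2
  gi <- adjacency_graph(3, rbind(c(1, 2)))
  Qi <- icar_precision(gi)
  expect_equal(as.vector(Qi$matrix[3, ]), c(0, 0, 0))
  expect_gte(ncol(Qi$null_space_basis), 2)

  # two disjoint edges on 4 nodes: rank n - c = 2
  g4 <- adjacency_graph(4, rbind(c(1, 2), c(3, 4)))
  Q4 <- icar_precision(g4)
  expect_equal(Q4$rank, 2)
  # kernel is spanned by the component indicators
  expect_lt(max(abs(Q4$matrix %*% c(1, 1, 0, 0))), 1e-12)
  expect_lt(max(abs(Q4$matrix %*% c(0, 0, 1, 1))), 1e-12)
})

test_that("interaction precisions are Kronecker products with product ranks", {
  A <- 6; T <- 5
  Qs <- icar_precision(lattice_graph(2, 3))
  Qt <- rw_precision(T, 1)
  QI <- interaction_precision("I", Qs, Qt)
  expect_equal(QI$rank, A * T)
  expect_equal(as.matrix(QI$matrix), diag(A * T), ignore_attr = TRUE)
  QII <- interaction_precision("II", Qs, Qt)
  expect_equal(QII$rank, A * (T - 1))
  QIII <- interaction_precision("III", Qs, Qt)
  expect_equal(QIII$rank, (A - 1) * T)
  QIV <- interaction_precision("IV", Qs, Qt)
  expect_equal(QIV$rank, (A - 1) * (T - 1))
  expect_error(interaction_precision("V", Qs, Qt), "unknown")

  # every claimed kernel vector is annihilated
  for (Q in list(QII, QIII, QIV)) {
    if (ncol(Q$null_space_basis)) {
      expect_lt(max(abs(Q$matrix %*% Q$null_space_basis)), 1e-8)
    }
    expect_equal(Q$rank + ncol(Q$null_space_basis), A * T)
  }
})

test_that("constraint systems match the effect kernels", {
  d <- study_dims(2, 3, 5, 4, M = 1)
  g <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
  spec <- model_spec(d, interaction_type = "IV")
  cons <- constraint_set(spec, g)
  expect_equal(nrow(cons$alpha), 2)          # one per gender
  expect_equal(ncol(cons$alpha), 2 * d$T)
  expect_equal(nrow(cons$phi), 1)            # connected graph
  # type IV row+column system has rank A + T - 1 = 6
  expect_equal(qr(cons$delta)$rank, d$A + d$T - 1)
  specI <- model_spec(d, interaction_type = "I")
  expect_equal(nrow(constraint_set(specI, g)$delta), 1)
})

test_that("constraint projection is idempotent and kernel-exact", {
  expect_equal(constrain(c(1, 2, 3), matrix(1, 1, 3)), c(-1, 0, 1))
  v <- constrain(c(1, 2, 3), matrix(1, 1, 3))
  expect_equal(constrain(v, matrix(1, 1, 3)), v)

  # type IV constraints on a 3 x 4 interaction grid (area-major order)
  d <- study_dims(1, 3, 2, 4, M = 1)
  spec <- model_spec(d, interaction_type = "IV")
  g <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
  Cmat <- constraint_set(spec, g)$delta
  set.seed(7)
  x <- rnorm(12)
  px <- constrain(x, Cmat)
  m <- matrix(px, nrow = 4)     # columns are areas (period fastest)
  expect_lt(max(abs(colSums(m))), 1e-12)  # per-area sums over periods
  expect_lt(max(abs(rowSums(m))), 1e-12)  # per-period sums over areas
  # matches a brute-force least-squares projection oracle built from an
  # independent subset of the constraint rows
  piv <- qr(t(Cmat))
  Cfull <- Cmat[piv$pivot[seq_len(piv$rank)], , drop = FALSE]
  oracle <- x - t(Cfull) %*% solve(Cfull %*% t(Cfull), Cfull %*% x)
  expect_equal(px, as.vector(oracle), tolerance = 1e-10)

  # projection never increases a PSD quadratic form below zero
  Q <- as.matrix(rw_precision(12, 1)$matrix)
  expect_gte(as.numeric(t(px) %*% Q %*% px), -1e-12)
})

test_that("the linear predictor assembles the log-linear decomposition", {
  d <- study_dims(2, 3, 4, 5, M = 1)
  ds <- simulate_gapc_dataset(model_spec(d, interaction_type = "I"),
                              adjacency_graph(3, rbind(c(1, 2), c(2, 3))),
                              seed = 5)$dataset

  # all effects zero and beta = log(1e-5): rate 1 per 100,000 everywhere
  ef0 <- effect_set(beta = rep(log(1e-5), 2), dims = d)
  lp0 <- linear_predictor(ef0, ds)
  expect_equal(exp(unique(as.vector(lp0$log_rate))) * 1e5, 1)
  expect_equal(lp0$log_mean, lp0$log_rate + log(ds$population))

  # a random effect set matches a naive quadruple-loop oracle
  set.seed(11)
  ef <- effect_set(
    beta = rnorm(2),
    alpha = matrix(rnorm(5 * 2), 5, 2),
    gamma = matrix(rnorm(4 * 2), 4, 2),
    kappa = matrix(rnorm(d$K * 2), d$K, 2),
    phi = rnorm(3),
    delta = matrix(rnorm(15), 3, 5),
    dims = d
  )
  lp <- linear_predictor(ef, ds)
  oracle <- array(NA_real_, dim = c(2, 3, 4, 5))
  for (g in 1:2) for (a in 1:3) for (i in 1:4) for (t in 1:5) {
    k <- d$M * (d$I - i) + t
    oracle[g, a, i, t] <- ef$beta[g] + ef$alpha[t, g] + ef$gamma[i, g] +
      ef$kappa[k, g] + ef$phi[a] + ef$delta[a, t]
  }
  expect_equal(lp$log_rate, oracle, tolerance = 1e-12)

  # perturbing phi shifts all cells of that area equally, in both genders
  ef2 <- ef; ef2$phi[2] <- ef2$phi[2] + 0.1
  lp2 <- linear_predictor(ef2, ds)
  diffs <- lp2$log_rate - lp$log_rate
  expect_equal(unique(round(as.vector(diffs[, 2, , ]), 12)), 0.1)
  expect_equal(max(abs(diffs[, -2, , ])), 0)
})

test_that("model specifications round-trip through YAML", {
  d <- study_dims(2, 9, 4, 6)
  spec <- model_spec(d, interaction_type = "II",
                     rw_order = list(alpha = 2, gamma = 1, kappa = 2),
                     shared_gender_precision = FALSE,
                     priors = prior_config(family = "uniform_sd",
                                           sigma_max = 10))
  path <- file.path(withr::local_tempdir(), "spec.yaml")
  write_model_spec(spec, path)
  spec2 <- read_model_spec(path)
  expect_equal(spec2$dims$K, spec$dims$K)
  expect_equal(spec2$rw_order, spec$rw_order)
  expect_equal(spec2$interaction_type, "II")
  expect_equal(spec2$priors$family, "uniform_sd")
  expect_false(spec2$shared_gender_precision)
})
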