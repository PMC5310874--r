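## MCMC engine for the spatial gender-age-period-cohort Poisson model.
##
## Sampler design: Metropolis-within-Gibbs over three latent blocks - one
## "gender block" per gender holding (beta_g, alpha_.g, gamma_.g, kappa_.g)
## jointly, a spatial block phi, and an interaction block delta.  Each block
## is updated with an independence Metropolis-Hastings proposal: Newton
## iteration to the mode of its full conditional, then a draw from the
## Gaussian approximation there, conditioned on the sum-to-zero constraint
## system by kriging, so every retained draw satisfies the constraints to
## machine precision.  Updating a gender's intercept and its age, period
## and cohort curves in one block captures their strong posterior
## correlation, which separate updates mix through only slowly.
##
## Precision hyperparameters move by an independence step from the matched
## Gamma kernel (acceptance ratio = prior ratio), interleaved with a joint
## (tau, effect) "one-block" move that breaks the amplitude-precision
## correlation.  Likelihood-invariant "ridge" moves interweave the
## directions left flat by the APC linear-trend aliasing and by the
## confounding between phi / alpha and an unstructured interaction.

chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# Sum `values` by integer group in 1..len (groups may be empty).
grp_sum <- function(values, group, len) {
  out <- numeric(len)
  rs <- rowsum(values, group)
  out[as.integer(rownames(rs))] <- rs
  out
}

# Cholesky with escalating jitter; precision matrices here are positive
# definite in exact arithmetic but near-singular H can arise transiently.
safe_chol <- function(H) {
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(H + diag(j * (mean(diag(H)) + 1), nrow(H))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("adaptation failure: proposal precision not positive definite",
       call. = FALSE)
}

# Orthonormalise constraint rows (drops redundancy, e.g. the type IV
# row+column system has rank A + T - 1).
reduce_constraints <- function(Cmat) {
  if (is.null(Cmat) || nrow(Cmat) == 0) return(matrix(0, 0, ncol(Cmat)))
  sv <- svd(Cmat, nu = 0)
  r <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  t(sv$v[, seq_len(r), drop = FALSE])
}

# Effective GMRF dimension of one segment under its sum-to-zero rows: the
# rank of Z' Q Z with Z spanning the constraint null space.  This is the
# exponent of tau in the generalised prior density.
segment_m_eff <- function(Qd, A_seg) {
  Z <- if (nrow(A_seg)) constraint_null_basis(A_seg) else diag(nrow(Qd))
  P <- crossprod(Z, Qd %*% Z)
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > max(abs(ev), 1e-12) * STRUCT_EIG_TOL)
}

# A latent block groups one or more effect "segments" that are updated
# jointly.  `U` (sparse, cells x len) maps the stacked block vector to its
# additive contribution to eta on the block's cells.
new_segment <- function(effect, gender, len, Qd, tau_param, A_seg) {
  list(effect = effect, gender = gender, len = len, Qd = Qd,
       tau_param = tau_param, m_eff = segment_m_eff(Qd, A_seg))
}

build_block <- function(name, segments, cells, maps, cons_rows) {
  len <- sum(vapply(segments, `[[`, 0L, "len"))
  off <- 0L
  ii <- list(); jj <- list()
  Arows <- list()
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    segments[[s]]$offset <- off
    ii[[s]] <- seq_along(cells)
    jj[[s]] <- off + maps[[s]]
    if (!is.null(cons_rows[[s]])) {
      cr <- cons_rows[[s]]
      full <- matrix(0, nrow(cr), len)
      full[, off + seq_len(seg$len)] <- cr
      Arows[[length(Arows) + 1L]] <- full
    }
    off <- off + seg$len
  }
  A_red <- reduce_constraints(
    if (length(Arows)) do.call(rbind, Arows) else matrix(0, 0, len))
  single <- length(segments) == 1L
  out <- list(name = name, segments = segments, cells = cells, len = len,
              single = single, A_red = A_red, x = numeric(len))
  if (single) {
    # one entry per cell: likelihood Hessian is diagonal
    out$ml <- maps[[1]]
  } else {
    U <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(length(cells), len))
    out$Ud <- as.matrix(U)
  }
  out
}

# Additive contribution of a block's stacked vector to eta on its cells.
block_eta <- function(b, x) {
  if (b$single) x[b$ml] else as.vector(b$Ud %*% x)
}

# Gradient and likelihood Hessian of a block at x.
block_grad_hess <- function(b, x, yc, er) {
  mu <- exp(pmin(er + block_eta(b, x), 27))
  if (b$single) {
    list(gx = grp_sum(yc - mu, b$ml, b$len),
         w_diag = grp_sum(mu, b$ml, b$len), Hlik = NULL)
  } else {
    list(gx = as.vector(crossprod(b$Ud, yc - mu)),
         w_diag = NULL, Hlik = crossprod(b$Ud * sqrt(mu)))
  }
}

# Dense prior precision of a block at the current taus.
block_prior_prec <- function(b, taus) {
  P <- matrix(0, b$len, b$len)
  for (seg in b$segments) {
    r <- seg$offset + seq_len(seg$len)
    tau <- if (is.na(seg$tau_param)) 1 else taus[[seg$tau_param]]
    P[r, r] <- tau * seg$Qd
  }
  P
}

# Prior log-density terms (quadratic part only) of a block.
block_prior_quad <- function(b, x, taus) {
  out <- 0
  for (seg in b$segments) {
    r <- seg$offset + seq_len(seg$len)
    tau <- if (is.na(seg$tau_param)) 1 else taus[[seg$tau_param]]
    out <- out - 0.5 * tau * sum(x[r] * (seg$Qd %*% x[r]))
  }
  out
}

# Quadratic form x' Q x of the segments attached to one precision.
tau_quad <- function(state, nm) {
  out <- 0
  for (ref in state$prec[[nm]]$refs) {
    b <- state$blocks[[ref$block]]
    seg <- b$segments[[ref$segment]]
    r <- seg$offset + seq_len(seg$len)
    out <- out + sum(b$x[r] * (seg$Qd %*% b$x[r]))
  }
  out
}

current_taus <- function(state) lapply(state$prec, `[[`, "tau")

## ---- model assembly ------------------------------------------------------

build_gapc_state <- function(dataset, graph, spec, fixed_tau = list()) {
  d <- spec$dims
  dd <- dataset$dims
  if (!identical(unclass(d)[c("G", "A", "I", "T", "M")],
                 unclass(dd)[c("G", "A", "I", "T", "M")])) {
    stop("structural error: spec dims and dataset dims disagree", call. = FALSE)
  }
  if (!is.null(graph) && graph$n != d$A) {
    stop("structural error: graph node count differs from number of areas",
         call. = FALSE)
  }
  needs_graph <- "phi" %in% spec$effects ||
    spec$interaction_type %in% c("III", "IV")
  if (needs_graph && is.null(graph)) {
    stop("this model needs an adjacency graph (phi or spatially structured interaction)",
         call. = FALSE)
  }

  idx <- cell_index_table(d)
  blocks <- list()

  rw_Q <- function(effect) {
    n <- switch(effect, alpha = d$T, gamma = d$I, kappa = d$K)
    as.matrix(rw_precision(n, spec$rw_order[[effect]])$matrix)
  }

  # one joint block per gender: beta_g plus its APC curves
  for (g in seq_len(d$G)) {
    cells <- which(idx$g == g)
    segs <- list(new_segment("beta", g, 1L,
                             matrix(1 / spec$priors$intercept_var, 1, 1),
                             NA_character_, matrix(0, 0, 1)))
    maps <- list(rep(1L, length(cells)))
    cons <- list(NULL)
    for (e in c("alpha", "gamma", "kappa")) {
      if (!e %in% spec$effects) next
      Qd <- rw_Q(e)
      tau_nm <- if (spec$shared_gender_precision) e else
        sprintf("%s_%s", e, dataset$labels$gender[g])
      segs[[length(segs) + 1L]] <-
        new_segment(e, g, nrow(Qd), Qd, tau_nm, sum_row(nrow(Qd)))
      maps[[length(maps) + 1L]] <-
        switch(e, alpha = idx$t, gamma = idx$i, kappa = idx$k)[cells]
      cons[[length(cons) + 1L]] <- sum_row(nrow(Qd))
    }
    names(segs) <- vapply(segs, `[[`, "", "effect")
    blocks[[sprintf("gender%d", g)]] <-
      build_block(sprintf("gender%d", g), segs, cells, maps, cons)
  }

  all_cells <- seq_len(nrow(idx))
  if ("phi" %in% spec$effects) {
    Qphi <- icar_precision(graph)
    cons_phi <- constraint_set(spec, graph)$phi
    blocks$phi <- build_block(
      "phi",
      list(phi = new_segment("phi", NA, d$A, as.matrix(Qphi$matrix),
                             "phi", cons_phi)),
      all_cells, list(idx$a), list(cons_phi))
  }
  if ("delta" %in% spec$effects) {
    Qt <- rw_precision(d$T, 1L)
    Qsp <- if (!is.null(graph)) icar_precision(graph) else NULL
    ident <- function(n) new_structure_matrix(Matrix::Diagonal(n),
                                              null_basis = matrix(0, n, 0))
    Qdel <- switch(spec$interaction_type,
      "I" = ident(d$A * d$T),
      "II" = interaction_precision("II", ident(d$A), Qt),
      "III" = interaction_precision("III", Qsp, ident(d$T)),
      "IV" = interaction_precision("IV", Qsp, Qt))
    cons_del <- constraint_set(spec, graph)$delta
    blocks$delta <- build_block(
      "delta",
      list(delta = new_segment("delta", NA, d$A * d$T,
                               as.matrix(Qdel$matrix), "delta", cons_del)),
      all_cells, list((idx$a - 1L) * d$T + idx$t), list(cons_del))
  }

  # precision parameters: collect the segments that share each one
  prec <- list()
  for (bn in names(blocks)) {
    for (sn in names(blocks[[bn]]$segments)) {
      seg <- blocks[[bn]]$segments[[sn]]
      nm <- seg$tau_param
      if (is.na(nm)) next
      if (is.null(prec[[nm]])) {
        fx <- fixed_tau[[seg$effect]]
        prec[[nm]] <- list(name = nm, refs = list(),
                           m_eff = 0,
                           tau = if (!is.null(fx)) fx else 25,
                           fixed = !is.null(fx),
                           step = 0.5,
                           joint_step = 1, jacc = 0L, jtries = 0L)
      }
      prec[[nm]]$refs[[length(prec[[nm]]$refs) + 1L]] <-
        list(block = bn, segment = sn)
      prec[[nm]]$m_eff <- prec[[nm]]$m_eff + seg$m_eff
    }
  }

  list(blocks = blocks, prec = prec, idx = idx,
       y = as.vector(dataset$deaths),
       off = log(as.vector(dataset$population)),
       spec = spec, graph = graph)
}

## ---- block updates -------------------------------------------------------

krige_project <- function(b, kr, v) {
  if (is.null(kr)) return(as.vector(v))
  # one step of iterative refinement: with badly conditioned H (e.g. a
  # precision near its upper bound) a single projection can leave residuals
  # around 1e-5; the second pass reduces them to machine precision
  v <- v - kr$V %*% chol_solve(kr$Rs, b$A_red %*% v)
  v <- v - kr$V %*% chol_solve(kr$Rs, b$A_red %*% v)
  res <- b$A_red %*% v
  if (max(abs(res)) > 1e-10 * max(1, max(abs(v)))) {
    # fall back to the Euclidean projection (A_red has orthonormal rows);
    # the correction is O(1e-10) and does not affect the proposal density
    # at working precision
    v <- v - t(b$A_red) %*% (b$A_red %*% v)
  }
  as.vector(v)
}

# Constrained Newton iteration to the mode of a block's full conditional;
# returns the mode and the Gaussian approximation there.
block_mode <- function(b, Pprior, yc, er) {
  xm <- b$x
  R <- NULL; kr <- NULL; m1 <- xm
  for (itn in seq_len(30L)) {
    gh <- block_grad_hess(b, xm, yc, er)
    gx <- gh$gx
    if (b$single) {
      H <- Pprior
      diag(H) <- diag(H) + gh$w_diag + 1e-12
    } else {
      H <- Pprior + gh$Hlik
      diag(H) <- diag(H) + 1e-12
    }
    R <- safe_chol(H)
    kr <- if (nrow(b$A_red)) {
      V <- chol_solve(R, t(b$A_red))        # H^-1 A'
      list(V = V, Rs = safe_chol(b$A_red %*% V))
    }
    m1 <- as.vector(xm + chol_solve(R, gx - Pprior %*% xm))
    xnew <- krige_project(b, kr, m1)
    step <- max(abs(xnew - xm))
    if (!is.finite(step)) return(NULL)
    xm <- xnew
    if (step < 1e-6) break
  }
  list(xm = xm, R = R, kr = kr, m1 = m1)
}

# Log-density of the kriged Gaussian proposal at a point on the constraint
# manifold; the terms shared by forward and reverse cancel in the
# acceptance ratio but are kept so the density is correct as stated.
proposal_logq <- function(b, md, v) {
  r <- as.vector(v - md$m1)
  out <- sum(log(diag(md$R))) - 0.5 * sum((md$R %*% r)^2)
  if (!is.null(md$kr)) {
    am <- b$A_red %*% md$m1
    out <- out + sum(log(diag(md$kr$Rs))) +
      0.5 * sum((backsolve(md$kr$Rs, am, transpose = TRUE))^2)
  }
  out
}

block_loglik <- function(b, x, yc, er) {
  e <- er + block_eta(b, x)
  sum(yc * e - exp(pmin(e, 300)))
}

update_block <- function(state, bname, eta) {
  b <- state$blocks[[bname]]
  taus <- current_taus(state)
  cells <- b$cells
  yc <- state$y[cells]
  er <- eta[cells] - block_eta(b, b$x)   # eta without this block
  Pprior <- block_prior_prec(b, taus)

  md <- block_mode(b, Pprior, yc, er)
  if (is.null(md)) return(list(block = b, eta = eta, accepted = FALSE))
  xs <- krige_project(b, md$kr, md$m1 + backsolve(md$R, stats::rnorm(b$len)))
  lp <- function(x) block_prior_quad(b, x, taus) + block_loglik(b, x, yc, er)
  log_acc <- (lp(xs) - lp(b$x)) +
    (proposal_logq(b, md, b$x) - proposal_logq(b, md, xs))
  if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
    b$x <- xs
    eta[cells] <- er + block_eta(b, xs)
    return(list(block = b, eta = eta, accepted = TRUE))
  }
  list(block = b, eta = eta, accepted = FALSE)
}

# Deterministic warm start: coordinate sweeps to the conditional modes so
# each chain starts where the Gaussian approximations are accurate.
warm_start <- function(state, eta, sweeps = 3L) {
  taus <- current_taus(state)
  for (s in seq_len(sweeps)) {
    for (bn in names(state$blocks)) {
      b <- state$blocks[[bn]]
      yc <- state$y[b$cells]
      er <- eta[b$cells] - block_eta(b, b$x)
      md <- block_mode(b, block_prior_prec(b, taus), yc, er)
      if (!is.null(md)) {
        state$blocks[[bn]]$x <- md$xm
        eta[b$cells] <- er + block_eta(b, md$xm)
      }
    }
  }
  list(state = state, eta = eta)
}

## ---- precision updates ---------------------------------------------------

# Independence MH from the matched Gamma kernel: the full conditional is
# tau^(m_eff/2) exp(-tau q / 2) * prior(tau), so proposing from
# Gamma(m_eff/2 + 1, q/2) leaves the prior ratio as the acceptance ratio.
update_precision <- function(state, nm) {
  p <- state$prec[[nm]]
  if (p$fixed) return(state)
  quad <- tau_quad(state, nm)
  if (quad > 1e-12) {
    tau_new <- stats::rgamma(1, shape = p$m_eff / 2 + 1, rate = quad / 2)
    la <- if (tau_new > 0 && tau_new < 1e10) {
      precision_logprior(tau_new, state$spec$priors) -
        precision_logprior(p$tau, state$spec$priors)
    } else -Inf
  } else {
    lt_new <- log(p$tau) + p$step * stats::rnorm(1)
    tau_new <- exp(lt_new)
    lt <- function(tau) {
      if (tau > 1e10) return(-Inf)
      precision_logprior(tau, state$spec$priors) + log(tau) +
        0.5 * p$m_eff * log(tau) - 0.5 * tau * quad
    }
    la <- lt(tau_new) - lt(p$tau)
  }
  if (is.finite(la) && log(stats::runif(1)) < la) state$prec[[nm]]$tau <- tau_new
  state
}

# Joint (tau, effect blocks) move: propose tau* by a log-scale random walk
# and re-propose every block containing a segment tied to tau* from its
# Gaussian approximation at the new value, accepting everything at once.
update_tau_joint <- function(state, nm, eta) {
  p <- state$prec[[nm]]
  if (p$fixed) return(list(state = state, eta = eta, accepted = FALSE))
  tau <- p$tau
  tau_new <- exp(log(tau) + p$joint_step * stats::rnorm(1))
  if (!is.finite(tau_new) || tau_new <= 0 || tau_new > 1e10) {
    return(list(state = state, eta = eta, accepted = FALSE))
  }
  taus <- current_taus(state)
  taus_new <- taus; taus_new[[nm]] <- tau_new
  la <- precision_logprior(tau_new, state$spec$priors) -
    precision_logprior(tau, state$spec$priors) +
    log(tau_new) - log(tau) +                  # log-scale Jacobian
    0.5 * p$m_eff * (log(tau_new) - log(tau))  # GMRF normalisation
  y <- state$y
  eta_new <- eta
  bns <- unique(vapply(p$refs, `[[`, "", "block"))
  prop <- list()
  for (bn in bns) {
    b <- state$blocks[[bn]]
    yc <- y[b$cells]
    er <- eta_new[b$cells] - block_eta(b, b$x)
    md_new <- block_mode(b, block_prior_prec(b, taus_new), yc, er)
    md_rev <- block_mode(b, block_prior_prec(b, taus), yc, er)
    if (is.null(md_new) || is.null(md_rev)) {
      return(list(state = state, eta = eta, accepted = FALSE))
    }
    xs <- krige_project(b, md_new$kr,
                        md_new$m1 + backsolve(md_new$R, stats::rnorm(b$len)))
    la <- la +
      (block_prior_quad(b, xs, taus_new) + block_loglik(b, xs, yc, er)) -
      (block_prior_quad(b, b$x, taus) + block_loglik(b, b$x, yc, er)) +
      (proposal_logq(b, md_rev, b$x) - proposal_logq(b, md_new, xs))
    if (!is.finite(la)) return(list(state = state, eta = eta, accepted = FALSE))
    eta_new[b$cells] <- er + block_eta(b, xs)
    prop[[bn]] <- xs
  }
  if (log(stats::runif(1)) < la) {
    for (bn in names(prop)) state$blocks[[bn]]$x <- prop[[bn]]
    state$prec[[nm]]$tau <- tau_new
    return(list(state = state, eta = eta_new, accepted = TRUE))
  }
  list(state = state, eta = eta, accepted = FALSE)
}

## ---- likelihood-invariant ridge moves ------------------------------------

# Metropolis step along a likelihood-invariant direction: `increments` maps
# block name -> increment of the block's stacked vector.  Acceptance
# depends only on the prior terms.
ridge_move <- function(state, increments) {
  taus <- current_taus(state)
  la <- 0
  for (nm in names(increments)) {
    b <- state$blocks[[nm]]
    la <- la + block_prior_quad(b, b$x + increments[[nm]], taus) -
      block_prior_quad(b, b$x, taus)
  }
  acc <- is.finite(la) && log(stats::runif(1)) < la
  if (acc) {
    for (nm in names(increments)) {
      state$blocks[[nm]]$x <- state$blocks[[nm]]$x + increments[[nm]]
    }
  }
  attr(state, "ridge_accepted") <- acc
  state
}

# place an increment into a segment of a block-sized zero vector
seg_inc <- function(b, segment, v) {
  out <- numeric(b$len)
  seg <- b$segments[[segment]]
  out[seg$offset + seq_len(seg$len)] <- v
  out
}

# APC linear aliasing: alpha tilts by s*(t - tbar), kappa by -s*(k - kbar),
# gamma by -s*M*(i - ibar); the leftover constant is absorbed into beta_g.
apc_ridge_increments <- function(state, g, s) {
  d <- state$spec$dims
  b <- state$blocks[[sprintf("gender%d", g)]]
  tt <- seq_len(d$T); ii <- seq_len(d$I); kk <- seq_len(d$K)
  c0 <- s * (mean(kk) - mean(tt) - d$M * (d$I - mean(ii)))
  inc <- seg_inc(b, "alpha", s * (tt - mean(tt))) +
    seg_inc(b, "kappa", -s * (kk - mean(kk))) +
    seg_inc(b, "gamma", -s * d$M * (ii - mean(ii))) +
    seg_inc(b, "beta", -c0)
  stats::setNames(list(inc), sprintf("gender%d", g))
}

# phi_a -> phi_a + c_a, delta_at -> delta_at - c_a (c centred within graph
# components); valid for interaction types whose constraints it preserves.
phi_delta_increments <- function(state, cvec) {
  d <- state$spec$dims
  comp <- state$graph$components
  cvec <- cvec - stats::ave(cvec, comp)
  list(phi = cvec, delta = -rep(cvec, each = d$T))
}

# alpha_tg -> alpha_tg + d_t (every gender), delta_at -> delta_at - d_t.
alpha_delta_increments <- function(state, dvec) {
  d <- state$spec$dims
  dvec <- dvec - mean(dvec)
  inc <- list(delta = -rep(dvec, times = d$A))
  for (g in seq_len(d$G)) {
    b <- state$blocks[[sprintf("gender%d", g)]]
    inc[[sprintf("gender%d", g)]] <- seg_inc(b, "alpha", dvec)
  }
  inc
}

## ---- main fitting routine ------------------------------------------------

#' Fit the spatial gender-age-period-cohort model by MCMC
#'
#' Runs a block Metropolis-within-Gibbs sampler (described in the package
#' vignette) on the Poisson model
#' `C_gait ~ Poisson(n_gait * r_gait)`,
#' `log r_gait = beta_g + alpha_tg + gamma_ig + kappa_kg + phi_a + delta_at`,
#' with the effects and priors declared in `spec`.  Sum-to-zero constraints
#' are enforced inside the sampler (conditioning-by-kriging on every block
#' proposal), so every retained draw satisfies the full constraint system.
#'
#' @param dataset A [mortality_dataset()].
#' @param graph An [adjacency_graph()] over the areas; may be `NULL` for
#'   models without `phi` or spatially structured interactions.
#' @param spec A [model_spec()].
#' @param chains Number of independent chains (default 2).
#' @param iterations Total iterations per chain (default 2000).
#' @param warmup Iterations discarded as warmup (default half); adaptation
#'   of Metropolis step sizes happens only during warmup.
#' @param seed Integer seed; runs are bit-reproducible given
#'   `(seed, chains, iterations)`.
#' @param fixed_tau Named list fixing the precision of selected effects
#'   (e.g. `list(alpha = 4)`), mainly for validation against small oracles.
#' @param verbose Print progress.
#' @return An object of class `gapc_fit` with elements `samples`
#'   (post-warmup draws: one draws-by-length matrix per effect, plus `tau`
#'   for the precisions), `chain_id`, `spec`, `labels`, `seed`, `accept`,
#'   and a `summary` data frame with posterior medians, means, standard
#'   deviations, central 95% intervals, ESS and split-Rhat per scalar.
#' @export
fit_gapc <- function(dataset, graph = NULL, spec, chains = 2L,
                     iterations = 2000L, warmup = floor(iterations / 2),
                     seed = 1L, fixed_tau = list(), verbose = FALSE) {
  stopifnot(inherits(dataset, "mortality_dataset"), inherits(spec, "model_spec"))
  iterations <- as.integer(iterations); warmup <- as.integer(warmup)
  if (iterations <= warmup) stop("iterations must exceed warmup", call. = FALSE)
  keep <- iterations - warmup
  state0 <- build_gapc_state(dataset, graph, spec, fixed_tau)
  d <- spec$dims

  # initial values: empirical gender log-rates for beta, zero elsewhere
  beta0 <- vapply(seq_len(d$G), function(g) {
    cells <- state0$idx$g == g
    log((sum(state0$y[cells]) + 0.5) / sum(exp(state0$off[cells])))
  }, 0)
  if (any(!is.finite(beta0))) {
    stop("initialization error: non-finite empirical log-rate", call. = FALSE)
  }
  for (g in seq_len(d$G)) state0$blocks[[sprintf("gender%d", g)]]$x[1] <- beta0[g]

  effect_names <- intersect(c("beta", "alpha", "gamma", "kappa", "phi", "delta"),
                            spec$effects)
  effect_len <- c(beta = d$G, alpha = d$T * d$G, gamma = d$I * d$G,
                  kappa = d$K * d$G, phi = d$A, delta = d$A * d$T)
  store <- lapply(effect_names, function(e)
    matrix(NA_real_, keep * chains, effect_len[[e]]))
  names(store) <- effect_names
  tau_store <- matrix(NA_real_, keep * chains, length(state0$prec),
                      dimnames = list(NULL, names(state0$prec)))
  chain_id <- integer(keep * chains)
  acc_blocks <- NULL

  ridge_cfg <- list(
    apc = all(c("alpha", "gamma", "kappa") %in% spec$effects),
    phidelta = all(c("phi", "delta") %in% spec$effects) &&
      spec$interaction_type %in% c("I", "III"),
    alphadelta = all(c("alpha", "delta") %in% spec$effects) &&
      spec$interaction_type %in% c("I", "II")
  )

  # gendered effects live as segments of the per-gender blocks
  collect_effect <- function(state, e) {
    if (e %in% c("phi", "delta")) return(state$blocks[[e]]$x)
    unlist(lapply(seq_len(d$G), function(g) {
      b <- state$blocks[[sprintf("gender%d", g)]]
      seg <- b$segments[[e]]
      b$x[seg$offset + seq_len(seg$len)]
    }), use.names = FALSE)
  }

  for (ch in seq_len(chains)) {
    set.seed(as.integer((abs(seed) + 104729 * ch) %% 2147483629) + 1L)
    state <- state0
    eta <- state$off + beta0[state$idx$g]
    if (any(!is.finite(eta))) {
      stop("initialization error: non-finite linear predictor", call. = FALSE)
    }
    ws <- warm_start(state, eta)
    state <- ws$state
    eta <- ws$eta
    bnames <- names(state$blocks)
    n_acc <- stats::setNames(numeric(length(bnames)), bnames)
    ridge_step <- c(apc = 0.02, phidelta = 0.05, alphadelta = 0.05)
    ridge_acc <- c(apc = 0, phidelta = 0, alphadelta = 0)
    ridge_try <- c(apc = 0, phidelta = 0, alphadelta = 0)

    for (it in seq_len(iterations)) {
      for (bn in bnames) {
        up <- update_block(state, bn, eta)
        state$blocks[[bn]] <- up$block
        eta <- up$eta
        n_acc[bn] <- n_acc[bn] + up$accepted
      }
      if (ridge_cfg$apc) {
        for (g in seq_len(d$G)) {
          s <- stats::rnorm(1, 0, ridge_step["apc"])
          state <- ridge_move(state, apc_ridge_increments(state, g, s))
          ridge_try["apc"] <- ridge_try["apc"] + 1
          ridge_acc["apc"] <- ridge_acc["apc"] + attr(state, "ridge_accepted")
        }
      }
      if (ridge_cfg$phidelta) {
        cv <- stats::rnorm(d$A, 0, ridge_step["phidelta"])
        state <- ridge_move(state, phi_delta_increments(state, cv))
        ridge_try["phidelta"] <- ridge_try["phidelta"] + 1
        ridge_acc["phidelta"] <- ridge_acc["phidelta"] + attr(state, "ridge_accepted")
      }
      if (ridge_cfg$alphadelta) {
        dv <- stats::rnorm(d$T, 0, ridge_step["alphadelta"])
        state <- ridge_move(state, alpha_delta_increments(state, dv))
        ridge_try["alphadelta"] <- ridge_try["alphadelta"] + 1
        ridge_acc["alphadelta"] <- ridge_acc["alphadelta"] + attr(state, "ridge_accepted")
      }
      for (nm in names(state$prec)) state <- update_precision(state, nm)
      if (it %% 3L == 0L) {
        for (nm in names(state$prec)) {
          res <- update_tau_joint(state, nm, eta)
          state <- res$state
          eta <- res$eta
          state$prec[[nm]]$jtries <- state$prec[[nm]]$jtries + 1L
          state$prec[[nm]]$jacc <- state$prec[[nm]]$jacc + res$accepted
        }
      }

      if (it <= warmup) {
        gam <- min(0.25, 3 / sqrt(it))
        for (nm in names(state$prec)) {
          p <- state$prec[[nm]]
          if (!p$fixed && p$jtries > 0) {
            rate <- p$jacc / p$jtries
            state$prec[[nm]]$joint_step <-
              min(4, max(0.05, exp(log(p$joint_step) + gam * (rate - 0.25))))
          }
        }
        for (rn in names(ridge_step)) {
          if (ridge_try[rn] > 0) {
            rate <- ridge_acc[rn] / ridge_try[rn]
            ridge_step[rn] <- exp(log(ridge_step[rn]) + gam * (rate - 0.44))
          }
        }
      } else {
        row <- (ch - 1L) * keep + (it - warmup)
        for (e in effect_names) store[[e]][row, ] <- collect_effect(state, e)
        tau_store[row, ] <- vapply(state$prec, `[[`, 0, "tau")
        chain_id[row] <- ch
      }
      if (verbose && it %% 500 == 0) {
        message(sprintf("chain %d iteration %d/%d", ch, it, iterations))
      }
    }
    acc_blocks <- rbind(acc_blocks, n_acc / iterations)
  }

  fit <- structure(list(
    samples = c(store, list(tau = tau_store)),
    chain_id = chain_id, keep = keep, chains = chains,
    iterations = iterations, warmup = warmup, seed = seed,
    spec = spec, dims = d, labels = dataset$labels,
    accept = acc_blocks
  ), class = "gapc_fit")
  fit$summary <- summarize_draws(fit)
  fit
}

#' @export
print.gapc_fit <- function(x, ...) {
  cat(sprintf("gapc_fit '%s': %d chains x %d draws (after %d warmup)\n",
              x$spec$name, x$chains, x$keep, x$warmup))
  cat(sprintf("  effects: %s; precisions: %s\n",
              paste(setdiff(names(x$samples), "tau"), collapse = ", "),
              paste(colnames(x$samples$tau), collapse = ", ")))
  invisible(x)
}

#' Posterior probability of exceeding a threshold
#'
#' Fraction of posterior draws strictly greater than `threshold`; used for
#' the exceedance maps `P(exp(phi_a) > 1)`.
#'
#' @param samples Numeric vector of draws of a scalar.
#' @param threshold Exceedance threshold.
#' @return A probability in `[0, 1]`.
#' @export
exceedance_probability <- function(samples, threshold) {
  if (length(samples) == 0) stop("no draws supplied", call. = FALSE)
  mean(samples > threshold)
}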