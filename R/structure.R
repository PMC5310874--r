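## Structural ingredients of the spatial gender-age-period-cohort model:
## cohort indexing, GMRF precision structures (random walks, ICAR,
## Knorr-Held space-time interactions), sum-to-zero constraint systems, and
## the log-linear predictor.

#' Cohort index of an (age group, period) cell
#'
#' With `I` age groups (youngest first) whose intervals are `M` times wider
#' than the period interval, the birth cohort of a cell is indexed by
#' `k = M * (I - i) + t`, ranging from 1 (oldest group, first period) to
#' `K = M * (I - 1) + T` (youngest group, last period).  Cells with equal
#' `k` lie on the same generalised diagonal: they differ by `dt = M * di`.
#'
#' @param i Age-group index (1 = youngest) in `1..I`; vectorised.
#' @param t Period index in `1..T`; vectorised.
#' @param dims A [study_dims()].
#' @return Integer cohort index in `1..K`.
#' @export
cohort_index <- function(i, t, dims) {
  if (any(i < 1 | i > dims$I) || any(i != round(i))) {
    stop("age index i out of range 1..I", call. = FALSE)
  }
  if (any(t < 1 | t > dims$T) || any(t != round(t))) {
    stop("period index t out of range 1..T", call. = FALSE)
  }
  as.integer(dims$M * (dims$I - i) + t)
}

## ---- structure matrices --------------------------------------------------

# Relative eigenvalue threshold used to decide numerical rank / kernel
# membership of precision structures.
STRUCT_EIG_TOL <- 1e-8

new_structure_matrix <- function(Q, null_basis = NULL) {
  Q <- as(Q, "CsparseMatrix")
  Q <- (Q + Matrix::t(Q)) / 2
  n <- nrow(Q)
  if (is.null(null_basis)) {
    ev <- eigen(as.matrix(Q), symmetric = TRUE)
    tol <- STRUCT_EIG_TOL * max(abs(ev$values), 1e-12)
    if (any(ev$values < -tol)) {
      stop("structure matrix is not positive semidefinite", call. = FALSE)
    }
    null <- ev$vectors[, ev$values < tol, drop = FALSE]
  } else {
    null <- as.matrix(null_basis)
    if (nrow(null) != n) stop("null basis dimension mismatch", call. = FALSE)
    if (ncol(null)) null <- qr.Q(qr(null))
  }
  structure(
    list(matrix = Q, rank = n - ncol(null), null_space_basis = null),
    class = "structure_matrix"
  )
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat(sprintf("structure_matrix: %d x %d, rank %d (kernel dim %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$rank,
              ncol(x$null_space_basis)))
  invisible(x)
}

#' Random-walk precision structure
#'
#' Returns the improper GMRF precision `t(D) %*% D` where `D` is the
#' `order`-th forward-difference operator on `1..n`.  The matrix has rank
#' `n - order`; its kernel is spanned by the polynomials of degree below
#' `order` (constants for RW1; constants and the linear trend for RW2).
#'
#' @param n Length of the effect vector (must exceed `order`).
#' @param order Random-walk order, 1 or 2.
#' @return A `structure_matrix` (sparse symmetric PSD matrix plus its rank
#'   and an orthonormal kernel basis).
#' @export
rw_precision <- function(n, order = 1L) {
  n <- as.integer(n); order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (n <= order) stop("need n > order for a random-walk structure", call. = FALSE)
  first_diff <- function(m) {
    Matrix::sparseMatrix(i = rep(seq_len(m - 1L), 2L),
                         j = c(seq_len(m - 1L), seq_len(m - 1L) + 1L),
                         x = rep(c(-1, 1), each = m - 1L),
                         dims = c(m - 1L, m))
  }
  D <- first_diff(n)
  if (order == 2L) D <- first_diff(n - 1L) %*% D
  # kernel: polynomials of degree < order
  null <- outer(seq_len(n), seq_len(order) - 1L, `^`)
  new_structure_matrix(Matrix::crossprod(D), null_basis = null)
}

#' Intrinsic CAR (Besag) precision structure
#'
#' Builds `Q = D - W`, the graph Laplacian of the area adjacency graph
#' (diagonal of neighbour counts minus the adjacency matrix).  Row sums are
#' zero; the rank is `n - c` where `c` is the number of connected
#' components, and the kernel is spanned by the component indicator
#' vectors.  An isolated node contributes an all-zero row and column.
#'
#' @param graph An [adjacency_graph()].
#' @return A `structure_matrix`.
#' @export
icar_precision <- function(graph) {
  n <- graph$n
  W <- Matrix::sparseMatrix(
    i = c(graph$edges[, 1], graph$edges[, 2]),
    j = c(graph$edges[, 2], graph$edges[, 1]),
    x = 1, dims = c(n, n)
  )
  Q <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  null <- vapply(seq_len(graph$n_components),
                 function(cc) as.numeric(graph$components == cc),
                 numeric(n))
  new_structure_matrix(Q, null_basis = matrix(null, nrow = n))
}

#' Knorr-Held space-time interaction precision structure
#'
#' The four interaction types are Kronecker products of structured or
#' unstructured space and time precisions, for an interaction vector
#' ordered area-major (all periods of area 1, then area 2, ...):
#' type I `I_A (x) I_T` (both unstructured), type II `I_A (x) Q_time`
#' (structured time within each area), type III `Q_space (x) I_T`
#' (structured space within each period), type IV `Q_space (x) Q_time`.
#' The rank is the product of the factor ranks.
#'
#' @param type One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param Q_space `structure_matrix` for the areas (`A x A`), e.g.
#'   [icar_precision()].
#' @param Q_time `structure_matrix` for the periods (`T x T`), e.g.
#'   [rw_precision()].
#' @return A `structure_matrix` of size `A*T`.
#' @export
interaction_precision <- function(type, Q_space, Q_time) {
  type <- as.character(type)
  A <- nrow(Q_space$matrix); T <- nrow(Q_time$matrix)
  IA <- Matrix::Diagonal(A); IT <- Matrix::Diagonal(T)
  eA <- Q_space$null_space_basis; eT <- Q_time$null_space_basis
  kron_null <- function(NA_, fullA, NT_, fullT) {
    # kernel of QA (x) QT is span{u (x) v : u in ker QA or v in ker QT}
    cols <- list()
    if (ncol(NA_)) for (j in seq_len(ncol(NA_))) {
      for (v in seq_len(ncol(fullT))) {
        cols[[length(cols) + 1L]] <- kronecker(NA_[, j], fullT[, v])
      }
    }
    if (ncol(NT_)) for (j in seq_len(ncol(NT_))) {
      for (u in seq_len(ncol(fullA))) {
        cols[[length(cols) + 1L]] <- kronecker(fullA[, u], NT_[, j])
      }
    }
    if (!length(cols)) return(matrix(0, A * T, 0))
    B <- do.call(cbind, cols)
    qrB <- qr(B)
    qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  }
  zA <- matrix(0, A, 0); zT <- matrix(0, T, 0)
  switch(type,
    "I" = new_structure_matrix(kronecker(IA, IT),
                               null_basis = matrix(0, A * T, 0)),
    "II" = new_structure_matrix(kronecker(IA, Q_time$matrix),
                                null_basis = kron_null(zA, diag(A), eT, diag(A))),
    "III" = new_structure_matrix(kronecker(Q_space$matrix, IT),
                                 null_basis = kron_null(eA, diag(A), zT, diag(T))),
    "IV" = new_structure_matrix(kronecker(Q_space$matrix, Q_time$matrix),
                                null_basis = kron_null(eA, diag(A), eT, diag(T))),
    stop(sprintf("unknown interaction type '%s'", type), call. = FALSE)
  )
}

## ---- model specification -------------------------------------------------

#' Specify a spatial gender-age-period-cohort model
#'
#' Declares which effects enter the log-linear predictor
#' `log r = beta_g + alpha_tg + gamma_ig + kappa_kg + phi_a + delta_at`,
#' the random-walk orders of the temporal (`alpha`), age (`gamma`) and
#' cohort (`kappa`) effects, the Knorr-Held type of the space-time
#' interaction `delta`, and the hyperprior configuration.  The spatial
#' effect `phi` and the interaction `delta` carry no gender subscript: they
#' are shared across genders.
#'
#' @param dims A [study_dims()].
#' @param effects Character vector naming the included effects, a subset of
#'   `c("beta", "alpha", "gamma", "kappa", "phi", "delta")`; `"beta"` is
#'   always included.
#' @param rw_order Named list of random-walk orders for `alpha`, `gamma`,
#'   `kappa`.  Defaults: RW1 for the period effect and RW2 for age and
#'   cohort (the standard smooth-APC choice; RW2 leaves linear trends
#'   unpenalised, which is what lets age and cohort curves be smooth).
#' @param interaction_type Knorr-Held type of `delta`: `"I"`, `"II"`,
#'   `"III"`, `"IV"`, or `"none"` (equivalent to dropping `delta`).
#' @param shared_gender_precision If `TRUE` (default) the gender-specific
#'   curves of one effect share a single precision hyperparameter;
#'   otherwise each gender gets its own.
#' @param priors A [prior_config()].
#' @param name Optional model label used in comparison tables.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(dims,
                       effects = c("beta", "alpha", "gamma", "kappa",
                                   "phi", "delta"),
                       rw_order = list(alpha = 1L, gamma = 2L, kappa = 2L),
                       interaction_type = "I",
                       shared_gender_precision = TRUE,
                       priors = prior_config(),
                       name = NULL) {
  stopifnot(inherits(dims, "study_dims"))
  known <- c("beta", "alpha", "gamma", "kappa", "phi", "delta")
  effects <- union("beta", match.arg(effects, known, several.ok = TRUE))
  if (identical(interaction_type, "none")) effects <- setdiff(effects, "delta")
  if (!"delta" %in% effects) interaction_type <- "none"
  if ("delta" %in% effects &&
      !interaction_type %in% c("I", "II", "III", "IV")) {
    stop("interaction_type must be one of I, II, III, IV or none", call. = FALSE)
  }
  ord <- list(alpha = 1L, gamma = 2L, kappa = 2L)
  ord[names(rw_order)] <- lapply(rw_order, as.integer)
  if (!all(unlist(ord) %in% c(1L, 2L))) {
    stop("random-walk orders must be 1 or 2", call. = FALSE)
  }
  if (any(c("alpha", "delta") %in% effects) && dims$T < 2L) {
    stop("period or interaction effects require T >= 2", call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste0("gapc_", paste(substr(setdiff(effects, "beta"), 1, 1),
                                  collapse = ""),
                   if (interaction_type != "none") paste0("_", interaction_type))
  }
  structure(
    list(dims = dims, effects = effects, rw_order = ord,
         interaction_type = interaction_type,
         shared_gender_precision = isTRUE(shared_gender_precision),
         priors = priors, name = name),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': effects {%s}, interaction %s\n", x$name,
              paste(x$effects, collapse = ", "), x$interaction_type))
  cat(sprintf("  rw orders: alpha=%d gamma=%d kappa=%d; %s gender precisions; priors: %s\n",
              x$rw_order$alpha, x$rw_order$gamma, x$rw_order$kappa,
              if (x$shared_gender_precision) "shared" else "per-gender",
              x$priors$family))
  invisible(x)
}

#' Serialise a model specification to YAML
#' @param spec A [model_spec()].
#' @param path Output path.
#' @export
write_model_spec <- function(spec, path) {
  d <- spec$dims
  yaml::write_yaml(list(
    dims = list(G = d$G, A = d$A, I = d$I, T = d$T, M = d$M),
    effects = spec$effects,
    rw_order = spec$rw_order,
    interaction_type = spec$interaction_type,
    shared_gender_precision = spec$shared_gender_precision,
    priors = unclass(spec$priors),
    name = spec$name
  ), path)
  invisible(path)
}

#' Read a model specification from YAML
#' @param path Path to a YAML file written by [write_model_spec()].
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  model_spec(
    dims = study_dims(G = y$dims$G, A = y$dims$A, I = y$dims$I,
                      T = y$dims$T, M = y$dims$M),
    effects = unlist(y$effects),
    rw_order = y$rw_order,
    interaction_type = y$interaction_type,
    shared_gender_precision = y$shared_gender_precision,
    priors = do.call(prior_config, y$priors),
    name = y$name
  )
}

## ---- constraint systems --------------------------------------------------

# Constraint matrix rows for one gender block of length n: a single
# sum-to-zero row.
sum_row <- function(n) matrix(1, nrow = 1, ncol = n)

# Replicate a per-gender constraint matrix across G stacked gender blocks.
stack_genders <- function(Amat, G) {
  if (G == 1L) return(Amat)
  out <- matrix(0, nrow = G * nrow(Amat), ncol = G * ncol(Amat))
  for (g in seq_len(G)) {
    out[(g - 1) * nrow(Amat) + seq_len(nrow(Amat)),
        (g - 1) * ncol(Amat) + seq_len(ncol(Amat))] <- Amat
  }
  out
}

#' Sum-to-zero constraint system of a model specification
#'
#' Emits, per included effect, the linear constraint matrix `C` such that
#' identifiable effect vectors satisfy `C x = 0`: one sum-to-zero row per
#' gender for `alpha`, `gamma` and `kappa`; one row per connected graph
#' component for `phi` (the global sum-to-zero on a connected graph); and,
#' for the interaction `delta` (ordered area-major), the family matching
#' its Knorr-Held kernel — type I a single global sum, type II one row per
#' area (sum over periods), type III one row per period (sum over areas),
#' type IV both families (rank `A + T - 1`).
#'
#' @param spec A [model_spec()].
#' @param graph An [adjacency_graph()], required when `phi` is included.
#' @return Named list of constraint matrices, one per constrained effect.
#' @export
constraint_set <- function(spec, graph = NULL) {
  d <- spec$dims
  out <- list()
  if ("alpha" %in% spec$effects) {
    out$alpha <- stack_genders(sum_row(d$T), d$G)
  }
  if ("gamma" %in% spec$effects) {
    out$gamma <- stack_genders(sum_row(d$I), d$G)
  }
  if ("kappa" %in% spec$effects) {
    out$kappa <- stack_genders(sum_row(d$K), d$G)
  }
  if ("phi" %in% spec$effects) {
    if (is.null(graph)) stop("phi constraints need the adjacency graph", call. = FALSE)
    out$phi <- t(vapply(seq_len(graph$n_components),
                        function(cc) as.numeric(graph$components == cc),
                        numeric(graph$n)))
  }
  if ("delta" %in% spec$effects) {
    A <- d$A; T <- d$T
    area_rows <- matrix(0, A, A * T)      # sum over t within each area
    for (a in seq_len(A)) area_rows[a, (a - 1) * T + seq_len(T)] <- 1
    period_rows <- matrix(0, T, A * T)    # sum over a within each period
    for (t in seq_len(T)) period_rows[t, t + T * (seq_len(A) - 1)] <- 1
    out$delta <- switch(spec$interaction_type,
      "I" = sum_row(A * T),
      "II" = area_rows,
      "III" = period_rows,
      "IV" = rbind(area_rows, period_rows)
    )
  }
  out
}

# Orthonormal basis of the null space of a constraint matrix (n columns).
constraint_null_basis <- function(Cmat) {
  n <- ncol(Cmat)
  sv <- svd(Cmat, nu = 0, nv = n)
  r <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  sv$v[, seq(r + 1, n), drop = FALSE]
}

#' Project a vector onto the null space of a constraint system
#'
#' Orthogonal (least-squares) projection of `x` onto `{v : C v = 0}`.
#' Idempotent; never increases any PSD quadratic form below zero.
#'
#' @param x Numeric vector.
#' @param constraints Constraint matrix `C` with `ncol(C) == length(x)`
#'   (redundant rows are tolerated and reduced internally).
#' @return The projected vector, satisfying `C %*% out == 0` to machine
#'   precision.
#' @export
constrain <- function(x, constraints) {
  Cmat <- as.matrix(constraints)
  if (ncol(Cmat) != length(x)) {
    stop("constraint matrix width must equal the vector length", call. = FALSE)
  }
  Z <- constraint_null_basis(Cmat)
  as.vector(Z %*% crossprod(Z, x))
}

## ---- effect sets and the linear predictor --------------------------------

#' Bundle of model effects
#'
#' @param beta Numeric vector of length `G`: gender-specific intercepts on
#'   the log-rate scale.
#' @param alpha `T x G` matrix of period effects (or `NULL`).
#' @param gamma `I x G` matrix of age effects.
#' @param kappa `K x G` matrix of cohort effects.
#' @param phi Length-`A` spatial effect, shared across genders.
#' @param delta `A x T` space-time interaction, shared across genders.
#' @param dims A [study_dims()] used to validate the shapes.
#' @return An object of class `effect_set`.
#' @export
effect_set <- function(beta, alpha = NULL, gamma = NULL, kappa = NULL,
                       phi = NULL, delta = NULL, dims) {
  stopifnot(inherits(dims, "study_dims"))
  chk <- function(x, nr, nc, nm) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (nrow(x) != nr || ncol(x) != nc) {
      stop(sprintf("structural error: %s must be %d x %d", nm, nr, nc),
           call. = FALSE)
    }
    x
  }
  if (length(beta) != dims$G) {
    stop("structural error: beta must have one entry per gender", call. = FALSE)
  }
  structure(list(
    beta = as.numeric(beta),
    alpha = chk(alpha, dims$T, dims$G, "alpha"),
    gamma = chk(gamma, dims$I, dims$G, "gamma"),
    kappa = chk(kappa, dims$K, dims$G, "kappa"),
    phi = if (is.null(phi)) NULL else {
      if (length(phi) != dims$A) stop("structural error: phi must have length A", call. = FALSE)
      as.numeric(phi)
    },
    delta = chk(delta, dims$A, dims$T, "delta")
  ), class = "effect_set")
}

#' Assemble the log-linear predictor
#'
#' Computes `log r_gait = beta_g + alpha_tg + gamma_ig + kappa_kg + phi_a +
#' delta_at` on the full grid (absent effects contribute zero), with the
#' cohort looked up through [cohort_index()], and the Poisson log-mean
#' `log mu = log n + log r`.
#'
#' @param effects An [effect_set()].
#' @param dataset A [mortality_dataset()] (provides dims and the offset).
#' @return List with 4-d arrays `log_rate` and `log_mean`.
#' @export
linear_predictor <- function(effects, dataset) {
  d <- dataset$dims
  idx <- cell_index_table(d)
  eta <- effects$beta[idx$g]
  if (!is.null(effects$alpha)) eta <- eta + effects$alpha[cbind(idx$t, idx$g)]
  if (!is.null(effects$gamma)) eta <- eta + effects$gamma[cbind(idx$i, idx$g)]
  if (!is.null(effects$kappa)) eta <- eta + effects$kappa[cbind(idx$k, idx$g)]
  if (!is.null(effects$phi)) eta <- eta + effects$phi[idx$a]
  if (!is.null(effects$delta)) eta <- eta + effects$delta[cbind(idx$a, idx$t)]
  log_rate <- array(eta, dim = c(d$G, d$A, d$I, d$T))
  list(log_rate = log_rate,
       log_mean = log_rate + log(dataset$population))
}
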