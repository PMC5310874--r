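# Shared fixtures for the test suite.  Everything is generated in code; the
# only packaged data are the national table fixture and the standard
# population weights shipped with the package itself.

# A tiny complete 2-gender, 1-area, 2-age, 2-period dataset.
tiny_dataset <- function() {
  deaths <- array(c(3, 5, 2, 4, 1, 6, 0, 2), dim = c(2, 1, 2, 2))
  population <- array(c(1e4, 1.1e4, 2e4, 2.1e4, 1.2e4, 1.3e4, 2.2e4, 2.3e4),
                      dim = c(2, 1, 2, 2))
  mortality_dataset(
    deaths = deaths, population = population,
    labels = list(gender = c("female", "male"), area = "A1",
                  age_group = c("[25,30)", "[30,35)"),
                  year = c("1990", "1991"))
  )
}

# Write the tiny dataset as a delimited file and return the path.
tiny_counts_file <- function(dir = NULL, sep = ",") {
  if (is.null(dir)) {
    dir <- tempfile("counts")
    dir.create(dir)
  }
  path <- file.path(dir, "counts.csv")
  write_counts(tiny_dataset(), path, sep = sep)
  path
}

# A hand-made posterior object with known draws, for summary oracles.
# draws: named list of matrices (beta, phi, delta...); absent effects NULL.
fake_fit <- function(draws, dims, labels = NULL, chains = 1L) {
  keep <- nrow(draws[[1]]) / chains
  if (is.null(labels)) {
    labels <- list(gender = paste0("g", seq_len(dims$G)),
                   area = paste0("a", seq_len(dims$A)),
                   age_group = sprintf("[%d,%d)",
                                       25 + 5 * (seq_len(dims$I) - 1),
                                       30 + 5 * (seq_len(dims$I) - 1)),
                   year = as.character(seq_len(dims$T)))
  }
  tau <- matrix(numeric(0), nrow(draws[[1]]), 0)
  fit <- structure(list(
    samples = c(draws, list(tau = tau)),
    chain_id = rep(seq_len(chains), each = keep),
    keep = keep, chains = chains,
    iterations = 2L * keep, warmup = keep, seed = 1L,
    spec = NULL, dims = dims, labels = labels, accept = NULL
  ), class = "gapc_fit")
  fit
}

# One moderately sized fitted model, computed once and reused by several
# test files (summaries, diagnostics, selection).  Cached in an environment
# so the suite pays the fitting cost a single time.
.bench_env <- new.env(parent = emptyenv())
benchmark_fit <- function() {
  if (is.null(.bench_env$fit)) {
    p <- gapc_preset("reduced")
    sim <- simulate_gapc_dataset(p$spec, p$graph, seed = 2024)
    .bench_env$sim <- sim
    .bench_env$preset <- p
    .bench_env$fit <- fit_gapc(sim$dataset, p$graph, p$spec, chains = 2L,
                               iterations = 700L, warmup = 300L, seed = 99L)
  }
  list(fit = .bench_env$fit, sim = .bench_env$sim, preset = .bench_env$preset)
}
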