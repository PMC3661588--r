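# Shared fixtures are simulated once per test run and memoised here; every
# fixture is generated in code, none is stored on disk.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

baseline_traj <- function() cached("baseline", simulate_remodeling())

baseline_traj_fine <- function() {
  cached("baseline_fine", simulate_remodeling(dt_out = 0.01))
}

# Random admissible parameter sets: positive rates, positive exponents on
# the unguarded bases, g43 free to be negative.
random_params <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    remodeling_params(
      alpha1 = runif(1, 0.05, 1), alpha2 = runif(1, 0.02, 0.5),
      alpha3 = runif(1, 0.02, 0.5), alpha4 = runif(1, 0.02, 0.5),
      beta1 = runif(1, 0.02, 0.5), beta2 = runif(1, 0.02, 0.5),
      beta3 = runif(1, 0.02, 0.5), delta = runif(1, 0.02, 0.5),
      K_S = runif(1, 50, 400), k1 = runif(1, 0.1, 2), k2 = runif(1, 0.005, 0.1),
      g31 = runif(1, 0.5, 2), g21 = runif(1, 1, 3), g22 = runif(1, 0.5, 2),
      g32 = runif(1, 0.5, 2), g41 = runif(1, 0.5, 2), g42 = runif(1, 0.5, 2),
      g43 = runif(1, -2, 0), g44 = runif(1, 0.5, 2),
      f12 = runif(1, 0.5, 2), f14 = runif(1, 0.5, 2),
      f23 = runif(1, 0.5, 2), f34 = runif(1, 0.5, 2),
      epsilon = runif(1, 0.5, 5))
  })
}

# Per-component sup error scaled by each component's overall magnitude.
scaled_max_error <- function(a, b) {
  vapply(colnames(a), function(cn)
    max(abs(a[, cn] - b[, cn])) / max(abs(a[, cn]), 1e-12), numeric(1))
}
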