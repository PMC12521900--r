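# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the reference CG melt with known potentials (the IBI ground truth);
# expensive, shared between the distribution, engine and acceptance tests
reference_melt_fixture <- function() {
  cached("reference_melt", function() generate_reference_melt(seed = 11))
}

# a small equilibrated melt for quick engine checks
small_melt_fixture <- function() {
  cached("small_melt", function() {
    topo <- cg_topology(10, 10)
    pots <- reference_potentials()
    st <- build_melt_configuration(topo, density = 930, seed = 3)
    st <- thermalize_velocities(st, 500, seed = 3)
    eq <- run_md(st, pots, topo, n_steps = 2000, temperature = 500,
                 friction = 5, seed = 1, min_steps = 500)
    list(topology = topo, potentials = pots, state = eq$state)
  })
}

# random loose chains with bonds near the table support, for force checks
random_chain_config <- function(n_chains = 2, N = 10, seed = 1, box = 5) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chains), function(c) {
      steps <- matrix(rnorm(3 * (N - 1)), N - 1, 3)
      steps <- steps / sqrt(rowSums(steps^2)) * 0.66
      start <- runif(3) * box
      rbind(start, sweep(matrix(apply(steps, 2, cumsum), N - 1, 3), 2, start, "+"))
    }))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
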