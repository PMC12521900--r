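test_that("table-derivative forces match finite-difference energy gradients", {
  topo <- cg_topology(10, 2)
  pots <- reference_potentials()
  pos <- random_chain_config(2, 10, seed = 42)
  box <- c(5, 5, 5)
  st <- engine_state(pos, box, bead_masses(topo))
  fc <- compute_forces(st, pots, topo)
  h <- 1e-6
  worst <- 0
  for (i in c(1, 5, 10, 11, 15, 20)) for (k in 1:3) {
    p1 <- pos; p1[i, k] <- p1[i, k] + h
    p2 <- pos; p2[i, k] <- p2[i, k] - h
    e1 <- compute_forces(engine_state(p1, box, st$masses), pots, topo)$energy
    e2 <- compute_forces(engine_state(p2, box, st$masses), pots, topo)$energy
    fd <- -(e1 - e2) / (2 * h)
    worst <- max(worst, abs(fd - fc$forces[i, k]) / max(1, abs(fd)))
  }
  expect_lt(worst, 1e-5)
})

test_that("bonded beads at the bond minimum feel no bond force; isolated beads none at all", {
  topo <- cg_topology(2, 1)
  r <- seq(0.4, 1.0, by = 0.005)
  pots <- potential_set(bond = tabulated_potential("bond", r, 0.5 * 2e4 * (r - 0.66)^2))
  pos <- rbind(c(1, 1, 1), c(1.66, 1, 1))
  fc <- compute_forces(engine_state(pos, c(5, 5, 5), bead_masses(topo)), pots, topo)
  expect_lt(max(abs(fc$forces)), 1e-6)

  lone <- cg_topology(1, 1)
  fc2 <- compute_forces(engine_state(matrix(1, 1, 3), c(5, 5, 5), 114),
                        reference_potentials(), lone)
  expect_equal(max(abs(fc2$forces)), 0)
})

test_that("zero potentials and zero friction give exact ballistic motion", {
  topo <- cg_topology(1, 5)
  pos <- matrix(runif(15, 1, 4), 5, 3)
  v <- matrix(rnorm(15, sd = 0.5), 5, 3)
  st <- engine_state(pos, c(10, 10, 10), rep(100, 5), velocities = v)
  out <- run_md(st, potential_set(), topo, n_steps = 100, dt = 0.01,
                temperature = 0, friction = 0, seed = 1)
  expect_equal(out$state$positions, pos + v * 1.0, tolerance = 1e-12)
  expect_equal(out$state$velocities, v, tolerance = 1e-14)
})

test_that("a thermostatted free bead satisfies equipartition at 500 K", {
  topo <- cg_topology(1, 1)
  st <- engine_state(matrix(2, 1, 3), c(5, 5, 5), 114.14)
  out <- run_md(st, potential_set(), topo, n_steps = 60000, dt = 0.005,
                temperature = 500, friction = 5, seed = 7, obs_stride = 10)
  ke <- out$observables$kinetic[-(1:50)]
  target <- 1.5 * kB * 500              # 6.236 kJ/mol
  # correlation time ~ 1/friction; effective samples ~ n * dt_obs * friction
  n_eff <- length(ke) * 0.05 * 5
  se <- sd(ke) / sqrt(n_eff)
  expect_lt(abs(mean(ke) - target), 3 * se + 0.02 * target)
  expect_equal(target, 6.236, tolerance = 1e-3)
})

test_that("a harmonic dimer samples the r^2-weighted Boltzmann bond density", {
  topo <- cg_topology(2, 1)
  k <- 2000; r0 <- 0.66; Tk <- 500
  r <- seq(0.2, 1.4, by = 0.005)
  pots <- potential_set(bond = tabulated_potential("bond", r, 0.5 * k * (r - r0)^2))
  st <- engine_state(rbind(c(2, 2, 2), c(2.66, 2, 2)), c(8, 8, 8),
                     rep(114.14, 2))
  out <- run_md(st, pots, topo, n_steps = 200000, dt = 0.005, temperature = Tk,
                friction = 2, seed = 3, obs_stride = 1000, traj_stride = 40)
  bl <- vapply(out$trajectory$frames, function(fr)
    sqrt(sum((fr$positions[2, ] - fr$positions[1, ])^2)), numeric(1))
  bl <- bl[-(1:100)]
  # reference sample from the exact density P(r) ~ r^2 exp(-U/kT)
  dens <- function(x) x^2 * exp(-0.5 * k * (x - r0)^2 / (kB * Tk))
  xs <- seq(0.3, 1.1, by = 1e-4)
  cdf <- cumsum(dens(xs)); cdf <- cdf / cdf[length(cdf)]
  ref <- withr::with_seed(5, approx(cdf, xs, runif(4000), ties = "ordered")$y)
  # thin the MD series to reduce autocorrelation, then two-sample KS at 1%
  ks <- suppressWarnings(stats::ks.test(bl[seq(1, length(bl), by = 10)], ref))
  expect_gt(ks$p.value, 0.01)
  # moments agree too
  expect_lt(abs(mean(bl) - mean(ref)), 3 * sd(ref) / sqrt(300) + 0.003)
})

test_that("NVE conserves energy and momentum for the reference melt", {
  sm <- small_melt_fixture()
  nve <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 10000,
                dt = 0.002, temperature = 0, friction = 0, seed = 1,
                obs_stride = 20)
  E <- nve$observables$kinetic + nve$observables$potential
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
  p0 <- colSums(sm$state$velocities * sm$state$masses)
  p1 <- colSums(nve$state$velocities * nve$state$masses)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("the thermostat holds the melt within 2% of 500 K over 50 000 steps", {
  sm <- small_melt_fixture()
  out <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 50000,
                dt = 0.005, temperature = 500, friction = 5, seed = 9,
                obs_stride = 50)
  Tbar <- mean(out$observables$temperature[-(1:100)])
  expect_lt(abs(Tbar - 500) / 500, 0.02)
})

test_that("identical seeds reproduce the observable series bit for bit", {
  sm <- small_melt_fixture()
  a <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 500,
              temperature = 500, friction = 5, seed = 123, obs_stride = 10)
  b <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 500,
              temperature = 500, friction = 5, seed = 123, obs_stride = 10)
  expect_identical(a$observables, b$observables)
  expect_identical(a$state$positions, b$state$positions)
  c <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 500,
              temperature = 500, friction = 5, seed = 124, obs_stride = 10)
  expect_false(identical(a$observables$kinetic, c$observables$kinetic))
})

test_that("non-interacting beads reproduce the ideal-gas pressure", {
  n <- 400
  topo <- cg_topology(1, n)
  L <- 6
  pos <- withr::with_seed(2, matrix(runif(3 * n, 0, L), ncol = 3))
  st <- engine_state(pos, rep(L, 3), rep(114.14, n))
  st <- thermalize_velocities(st, 500, seed = 2)
  out <- run_md(st, potential_set(), topo, n_steps = 20000, dt = 0.005,
                temperature = 500, friction = 2, seed = 11, obs_stride = 20)
  P <- out$observables$pressure[-(1:100)]
  P_ideal <- n / L^3 * kB * 500 * 16.6054    # rho kB T in bar
  n_eff <- length(P) * 0.1 * 2
  se <- sd(P) / sqrt(n_eff)
  expect_lt(abs(mean(P) - P_ideal), 3 * se + 0.01 * P_ideal)

  # a static single bead has exactly zero pressure
  one <- engine_state(matrix(1, 1, 3), c(5, 5, 5), 100)
  expect_equal(measure_pressure(one, potential_set(), cg_topology(1, 1)), 0)

  # a purely repulsive pair inside the cutoff raises P above ideal gas
  r <- seq(0.3, 1.5, 0.005)
  rep_pot <- potential_set(nonbonded = tabulated_potential("nonbonded", r,
                                                           5 * exp(-5 * r)))
  two <- cg_topology(1, 2)
  stp <- engine_state(rbind(c(1, 1, 1), c(1.5, 1, 1)), c(4, 4, 4), c(100, 100))
  expect_gt(measure_pressure(stp, rep_pot, two), 0)
})

test_that("the weak-coupling barostat drives the box toward the target pressure", {
  sm <- small_melt_fixture()
  out <- run_md(sm$state, sm$potentials, sm$topology, n_steps = 20000,
                dt = 0.005, temperature = 500, friction = 5, pressure = 1,
                seed = 5, obs_stride = 100, tau_p = 2)
  P_late <- mean(tail(out$observables$pressure, 50))
  P_early <- mean(head(out$observables$pressure, 20))
  expect_lt(abs(P_late - 1), abs(P_early - 1) + 50)
  expect_false(identical(out$state$box, sm$state$box))
})
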