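#' Engine state of a CG melt simulation
#'
#' Positions (nm), velocities (nm/ps), orthorhombic box (nm), bead masses
#' (g/mol) and time (ps). Positions are kept unwrapped: the minimum-image
#' convention handles periodicity during force evaluation, and analyses that
#' need contiguous molecules (centers of mass, mean squared displacements)
#' then need no unwrapping step.
#'
#' @param positions `n x 3` matrix, nm.
#' @param velocities `n x 3` matrix, nm/ps; zeros if omitted.
#' @param box length-3 edges, nm.
#' @param masses per-bead masses, g/mol.
#' @param time ps.
#' @export
engine_state <- function(positions, box, masses, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == dim(positions)))
    stop("velocity array must be congruent with positions")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  box <- as.numeric(box); if (length(box) == 1) box <- rep(box, 3)
  structure(list(positions = positions, velocities = velocities, box = box,
                 masses = as.numeric(masses), time = time),
            class = "engine_state")
}

#' Maxwell-Boltzmann velocities
#'
#' @param state an [engine_state()].
#' @param temperature K.
#' @param seed RNG seed (uses R's RNG through a local seed).
#' @export
thermalize_velocities <- function(state, temperature, seed = 1) {
  n <- nrow(state$positions)
  v <- withr::with_seed(seed, matrix(rnorm(3 * n), n, 3))
  v <- v * sqrt(kB * temperature / state$masses)
  v <- sweep(v, 2, colSums(v * state$masses) / sum(state$masses))  # zero momentum
  state$velocities <- v
  state
}

engine_params <- function(dt = 0.005, n_steps = 1000, temperature = 500,
                          friction = 1, pressure = NA_real_, tau_p = 1,
                          kappa = 4.5e-5, rcut = 1.5, skin = 0.3,
                          excl_bonds = 3L, obs_stride = 10L, traj_stride = 0L,
                          min_steps = 0L, seed = 1, time0 = 0) {
  list(dt = dt, n_steps = as.integer(n_steps), temperature = temperature,
       friction = friction, pressure = pressure, tau_p = tau_p, kappa = kappa,
       rcut = rcut, skin = skin, excl_bonds = as.integer(excl_bonds),
       obs_stride = as.integer(obs_stride), traj_stride = as.integer(traj_stride),
       min_steps = as.integer(min_steps), seed = as.numeric(seed), time0 = time0)
}

#' Compute forces, potential energy and virial for a CG configuration
#'
#' Energies and forces come from the natural-cubic-spline interpolant of each
#' tabulated potential (forces are the exact analytic derivative of the
#' interpolated energy, so the force field is conservative). Bonded terms run
#' over consecutive bead tuples; nonbonded pairs use the same
#' more-than-`excl_bonds` intramolecular exclusion as the monomeric RDF, the
#' minimum-image convention and a plain cutoff (tables are built shifted to
#' zero there).
#'
#' @param state an [engine_state()].
#' @param potentials a [potential_set()].
#' @param topology a `system_topology` at bead resolution.
#' @param rcut nonbonded cutoff, nm.
#' @param excl_bonds intramolecular exclusion depth.
#' @return list with `forces` (kJ/mol/nm), `energy` (kJ/mol), `virial`.
#' @export
compute_forces <- function(state, potentials, topology, rcut = 1.5,
                           excl_bonds = 3L) {
  cpp_compute_forces(state$positions, state$box, bead_chain(topology) - 1L,
                     bead_index(topology) - 1L, tables_for_engine(potentials),
                     rcut, as.integer(excl_bonds))
}

#' Integrate the equations of motion of a tabulated-potential CG melt
#'
#' Velocity-Verlet core with an optional Langevin (stochastic friction)
#' thermostat and an optional isotropic weak-coupling barostat. With the
#' thermostat off (`friction = 0` or `temperature = 0`) the integrator is
#' plain NVE and conserves energy and total momentum. Identical seeds and
#' configurations reproduce trajectories bit for bit.
#'
#' @param state an [engine_state()].
#' @param potentials a [potential_set()].
#' @param topology bead-level `system_topology`.
#' @param n_steps number of MD steps.
#' @param dt time step, ps (default 0.005, i.e. 5 fs).
#' @param temperature thermostat target, K; 0 disables the thermostat.
#' @param friction Langevin friction, 1/ps.
#' @param pressure barostat target, bar; `NA` disables the barostat.
#' @param seed integer seed for the engine's own RNG stream.
#' @param obs_stride steps between observable records.
#' @param traj_stride steps between stored frames; 0 stores none.
#' @param min_steps steepest-descent minimization steps before dynamics.
#' @param rcut,skin,excl_bonds,tau_p,kappa engine numerics: nonbonded cutoff
#'   and neighbor-list skin (nm), exclusion depth, barostat time constant
#'   (ps) and compressibility (1/bar).
#' @return list with `state` (final [engine_state()]), `observables` (tibble:
#'   time, kinetic/potential energy kJ/mol, temperature K, pressure bar,
#'   density kg/m^3) and `trajectory` (a `cg_trajectory`, or `NULL`).
#' @export
run_md <- function(state, potentials, topology, n_steps, dt = 0.005,
                   temperature = 500, friction = 1, pressure = NA_real_,
                   seed = 1, obs_stride = 10L, traj_stride = 0L,
                   min_steps = 0L, rcut = 1.5, skin = 0.3, excl_bonds = 3L,
                   tau_p = 1, kappa = 4.5e-5) {
  par <- engine_params(dt = dt, n_steps = n_steps, temperature = temperature,
                       friction = friction, pressure = pressure, tau_p = tau_p,
                       kappa = kappa, rcut = rcut, skin = skin,
                       excl_bonds = excl_bonds, obs_stride = obs_stride,
                       traj_stride = traj_stride, min_steps = min_steps,
                       seed = seed, time0 = state$time)
  res <- cpp_run_md(state$positions, state$velocities, state$masses, state$box,
                    bead_chain(topology) - 1L, bead_index(topology) - 1L,
                    tables_for_engine(potentials), par)
  obs <- as_tibble(as.data.frame(res$observables))
  names(obs) <- c("time", "kinetic", "potential", "temperature", "pressure",
                  "density", "box_x")
  out_state <- engine_state(res$positions, res$box, state$masses,
                            velocities = res$velocities, time = res$time)
  traj <- NULL
  if (traj_stride > 0 && length(res$frames) > 0) {
    frames <- lapply(seq_along(res$frames), function(i)
      frame(res$frames[[i]], res$frame_box[i, ], res$frame_time[i]))
    traj <- as_cg_trajectory(trajectory(frames), topology)
  }
  list(state = out_state, observables = obs, trajectory = traj)
}

#' Instantaneous virial pressure of a configuration
#'
#' `P = (2/3 KE + 1/3 W) / V`, converted to bar, with the kinetic energy
#' taken from the state's velocities and the virial `W` from
#' [compute_forces()].
#'
#' @inheritParams compute_forces
#' @export
measure_pressure <- function(state, potentials, topology, rcut = 1.5,
                             excl_bonds = 3L) {
  V <- prod(state$box)
  if (V <= 0) stop("zero box volume")
  fc <- compute_forces(state, potentials, topology, rcut, excl_bonds)
  ke <- 0.5 * sum(state$masses * rowSums(state$velocities^2))
  (2 * ke / 3 + fc$virial / 3) / V * PRESS_UNIT
}

#' Build an initial melt configuration at a target density
#'
#' Chains are grown as freely jointed random walks with the requested bond
#' length, placed at random in a cubic box sized to the target mass density.
#' The configuration is not relaxed here; [run_md()] with `min_steps > 0`
#' removes overlaps before dynamics.
#'
#' @param topology bead-level `system_topology`.
#' @param density target mass density, kg/m^3.
#' @param bond_length initial bond length, nm.
#' @param seed RNG seed.
#' @return an [engine_state()].
#' @export
build_melt_configuration <- function(topology, density = 930,
                                     bond_length = 0.66, seed = 1) {
  masses <- bead_masses(topology)
  mtot <- sum(masses)                       # g/mol
  V <- mtot * 1.66053906892 / density       # nm^3
  L <- V^(1 / 3)
  N <- topology$N
  pos <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(topology$n_chains), function(c) {
      walk <- matrix(0, N, 3)
      if (N > 1) {
        steps <- matrix(rnorm(3 * (N - 1)), N - 1, 3)
        steps <- steps / sqrt(rowSums(steps^2)) * bond_length
        walk[-1, ] <- matrix(apply(steps, 2, cumsum), N - 1, 3)
      }
      sweep(walk, 2, runif(3) * L, "+")
    }))
  })
  engine_state(pos, rep(L, 3), masses)
}
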