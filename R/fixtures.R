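#' Generate ideal-chain ensembles
#'
#' Freely jointed (`fjc`) or freely rotating (`frc`) chains built by
#' sequential random bond vectors and dropped into a box at the requested
#' density with no excluded-volume relaxation: the theoretical baselines for
#' the static observables (`<Re^2> = (N-1) b^2` for the FJC; the closed-form
#' characteristic ratio for the FRC). Not a melt — use
#' [generate_reference_melt()] when packing matters.
#'
#' @param N monomers (beads) per chain.
#' @param n_chains chains in the ensemble.
#' @param bond_length bond length `b`, nm (default 0.66, the CG monomer
#'   spacing).
#' @param kind `"fjc"` or `"frc"`.
#' @param bond_angle fixed interior bond angle for `frc`, degrees in (0, 180).
#' @param density box mass density, kg/m^3 (box sizing only; chains may
#'   overlap).
#' @param bead_mass bead mass, g/mol.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a `cg_trajectory` with a single frame holding all chains, with
#'   its bead-level topology attached.
#' @export
generate_ideal_chains <- function(N, n_chains, bond_length = 0.66,
                                  kind = c("fjc", "frc"), bond_angle = NULL,
                                  density = 930, bead_mass = MONOMER_MASS_PCL,
                                  seed = 1) {
  kind <- match.arg(kind)
  if (kind == "frc") {
    if (is.null(bond_angle) || bond_angle <= 0 || bond_angle >= 180)
      stop("frc requires a bond angle strictly between 0 and 180 degrees")
  }
  topo <- cg_topology(N, n_chains, bead_mass)
  mtot <- n_chains * N * bead_mass
  L <- (mtot * 1.66053906892 / density)^(1 / 3)
  pos <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chains), function(c)
      sweep(one_ideal_chain(N, bond_length, kind, bond_angle), 2,
            runif(3) * L, "+")))
  })
  fr <- frame(pos, rep(L, 3), 0)
  as_cg_trajectory(trajectory(list(fr)), topo)
}

one_ideal_chain <- function(N, b, kind, bond_angle) {
  pos <- matrix(0, N, 3)
  if (N == 1) return(pos)
  if (kind == "fjc") {
    steps <- matrix(rnorm(3 * (N - 1)), N - 1, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * b
  } else {
    # successive bond vectors on a fixed cone: the angle between bonds is
    # the supplement of the interior bond angle
    gam <- pi - bond_angle * pi / 180
    steps <- matrix(0, N - 1, 3)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    steps[1, ] <- v * b
    for (i in seq_len(N - 2)) {
      t_prev <- steps[i, ] / b
      u <- perpendicular_unit(t_prev)
      w <- cross3(t_prev, u)
      phi <- runif(1, 0, 2 * pi)
      t_new <- cos(gam) * t_prev + sin(gam) * (cos(phi) * u + sin(phi) * w)
      steps[i + 1, ] <- t_new * b
    }
  }
  pos[-1, ] <- matrix(apply(steps, 2, cumsum), N - 1, 3)
  pos
}

perpendicular_unit <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(v, a)
  u / sqrt(sum(u^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Closed-form mean squared end-to-end distance of a freely rotating chain
#'
#' `<Re^2> = b^2 sum_{i,j} alpha^|i-j|` with `alpha = -cos(theta)` the
#' cosine of the angle between successive bond vectors (`theta` is the
#' interior bond angle), evaluated by direct summation over the `n = N - 1`
#' bonds. Used as the independent reference for the `frc` generator.
#'
#' @param N beads per chain.
#' @param bond_length nm.
#' @param bond_angle interior angle, degrees.
#' @export
frc_re2_exact <- function(N, bond_length, bond_angle) {
  n <- N - 1
  alpha <- -cos(bond_angle * pi / 180)
  idx <- seq_len(n)
  S <- sum(alpha^abs(outer(idx, idx, "-")))
  bond_length^2 * S
}

#' Reference-potential set of the synthetic CG melt
#'
#' Harmonic bond, cosine-harmonic angle, single-cosine dihedral and
#' truncated-shifted Lennard-Jones nonbonded interactions expressed as
#' tables, sized to mimic the CG monomer geometry (bond about 0.66 nm).
#'
#' @param k_bond harmonic bond constant, kJ/mol/nm^2.
#' @param r0 bond rest length, nm.
#' @param k_angle cosine-harmonic constant, kJ/mol.
#' @param theta0 rest angle, degrees.
#' @param k_dih single-cosine torsion barrier, kJ/mol (`T(phi) = k (1 + cos
#'   phi)`, trans minimum; the engine applies it in the combined
#'   bending-torsion form `T(phi) sin^3(theta1) sin^3(theta2)`).
#' @param sigma,epsilon Lennard-Jones parameters, nm and kJ/mol.
#' @param rcut nonbonded cutoff, nm (energy-shifted to zero there).
#' @param temperature K.
#' @export
reference_potentials <- function(k_bond = 20000, r0 = 0.66, k_angle = 50,
                                 theta0 = 135, k_dih = 4, sigma = 0.55,
                                 epsilon = 2.5, rcut = 1.5, temperature = 500) {
  rb <- seq(0.40, 1.00, by = 0.005)
  bond <- tabulated_potential("bond", rb, 0.5 * k_bond * (rb - r0)^2)
  th <- seq(0, 180, by = 1)
  angle <- tabulated_potential("angle", th,
                               0.5 * k_angle * (cos(th * pi / 180) -
                                                cos(theta0 * pi / 180))^2)
  ph <- seq(-180, 180, by = 2)
  dihedral <- tabulated_potential("dihedral", ph, k_dih * (1 + cos(ph * pi / 180)))
  rn <- seq(0.30, rcut, by = 0.005)
  lj <- 4 * epsilon * ((sigma / rn)^12 - (sigma / rn)^6)
  # quintic switch from 0.8 rcut: energy and force go smoothly to zero at the
  # cutoff, so the tabulated force field is strictly conservative
  rs <- 0.8 * rcut
  xx <- pmin(pmax((rn - rs) / (rcut - rs), 0), 1)
  lj <- lj * (1 - 10 * xx^3 + 15 * xx^4 - 6 * xx^5)
  nonbonded <- tabulated_potential("nonbonded", rn, lj)
  potential_set(bond, angle, dihedral, nonbonded, temperature = temperature)
}

#' Generate an equilibrated reference CG melt with known potentials
#'
#' Builds a melt of `n_chains` chains of `N` beads, equilibrates it with the
#' embedded engine under the [reference_potentials()] at the requested
#' temperature and fixed density, and measures the four target
#' distributions from the production run. This is the ground truth for the
#' coarse-graining recovery experiments: the measured distributions are the
#' targets, the generating potentials the known answer (up to additive
#' constants).
#'
#' @param N beads per chain (default 10).
#' @param n_chains chains (default 70).
#' @param temperature K (default 500).
#' @param density kg/m^3 (default 930, a CG melt density).
#' @param potentials a [potential_set()]; default [reference_potentials()].
#' @param equil_steps,prod_steps equilibration and production step counts.
#' @param sample_stride steps between sampled frames.
#' @param dt time step, ps.
#' @param friction Langevin friction, 1/ps.
#' @param seed engine seed.
#' @return list with `topology`, `potentials`, `trajectory` (production
#'   `cg_trajectory`), `distributions` (the measured [distribution_set()]),
#'   `final_state` and `observables`.
#' @export
generate_reference_melt <- function(N = 10, n_chains = 70, temperature = 500,
                                    density = 930,
                                    potentials = reference_potentials(temperature = temperature),
                                    equil_steps = 30000, prod_steps = 40000,
                                    sample_stride = 100, dt = 0.005,
                                    friction = 5, seed = 1) {
  topo <- cg_topology(N, n_chains)
  st <- build_melt_configuration(topo, density = density, bond_length = 0.66,
                                 seed = seed)
  st <- thermalize_velocities(st, temperature, seed = seed)
  eq <- run_md(st, potentials, topo, n_steps = equil_steps, dt = dt,
               temperature = temperature, friction = friction, seed = seed,
               obs_stride = 1000L, min_steps = 500L)
  pr <- run_md(eq$state, potentials, topo, n_steps = prod_steps, dt = dt,
               temperature = temperature, friction = friction, seed = seed + 1,
               obs_stride = 100L, traj_stride = sample_stride)
  dists <- measure_distributions(pr$trajectory, temperature = temperature)
  list(topology = topo, potentials = potentials, trajectory = pr$trajectory,
       distributions = dists, final_state = pr$state,
       observables = pr$observables)
}

#' Decorate CG configurations into pseudo-atomistic chains
#'
#' Replaces every bead by the PCL template's atoms (18 per internal monomer,
#' 19/20 at the ends, 7 backbone atoms per monomer) such that the
#' mass-weighted center of each monomer's atoms reproduces the parent bead
#' position exactly. Backbone atoms are laid out along the bond direction so
#' backbone indexing is meaningful; all offsets are then recentered
#' mass-weighted onto the bead.
#'
#' @param cgtraj a `cg_trajectory` (or single [frame()] plus `topology`).
#' @param topology bead-level topology when `cgtraj` is a bare frame.
#' @param spread spatial scale of the decoration offsets, nm.
#' @param seed RNG seed for the off-backbone offsets.
#' @return list with `trajectory` (atomistic-level [trajectory()]) and
#'   `topology` (the PCL-template `system_topology`).
#' @export
generate_decorated_chains <- function(cgtraj, topology = NULL, spread = 0.08,
                                      seed = 1) {
  if (inherits(cgtraj, "frame")) {
    stopifnot(!is.null(topology))
    cgtraj <- as_cg_trajectory(trajectory(list(cgtraj)), topology)
  }
  ctopo <- cgtraj$topology
  atopo <- build_pcl_topology(ctopo$N, ctopo$n_chains)
  atoms <- atopo$atoms
  if (any(tapply(atoms$mass, atopo$bead_of_atom, sum) <= 0))
    stop("decoration pattern must carry positive mass per monomer")
  # one fixed offset pattern per monomer slot, reused across chains/frames
  n_mono_atoms <- as.vector(table(atoms$monomer[atoms$chain == 1]))
  offsets <- withr::with_seed(seed, lapply(seq_len(ctopo$N), function(m) {
    k <- n_mono_atoms[m]
    matrix(rnorm(3 * k, sd = spread), k, 3)
  }))

  a1 <- atoms[atoms$chain == 1, ]
  frames <- lapply(cgtraj$frames, function(fr) {
    bead_pos <- fr$positions
    out <- matrix(NA_real_, nrow(atoms), 3)
    row0 <- 0L
    for (c in seq_len(ctopo$n_chains)) {
      for (m in seq_len(ctopo$N)) {
        bead <- bead_pos[(c - 1) * ctopo$N + m, ]
        nxt <- if (m < ctopo$N) bead_pos[(c - 1) * ctopo$N + m + 1, ] else
          2 * bead - bead_pos[(c - 1) * ctopo$N + m - 1, ]
        rows <- which(a1$monomer == m)
        k <- length(rows)
        off <- offsets[[m]]
        # backbone atoms strung along the bond direction
        bb <- a1$backbone[rows]
        off[bb, ] <- outer((seq_len(sum(bb)) - 1) / sum(bb) - 0.5, nxt - bead) +
          0.25 * off[bb, ]
        m_at <- a1$mass[rows]
        com_off <- colSums(off * m_at) / sum(m_at)
        off <- sweep(off, 2, com_off)
        out[row0 + seq_len(k), ] <- sweep(off, 2, bead, "+")
        row0 <- row0 + k
      }
    }
    frame(out, fr$box, fr$time)
  })
  list(trajectory = trajectory(frames), topology = atopo)
}

#' Generate a synthetic stretched-exponential relaxation curve
#'
#' `f(t) = A exp(-(t/tau)^beta)` plus seeded Gaussian noise; the test input
#' for [fit_kww()].
#'
#' @param A,tau,beta KWW parameters (within the fit bounds).
#' @param sigma Gaussian noise standard deviation.
#' @param times lag-time grid, ps.
#' @param seed RNG seed.
#' @return an `acf_curve` tibble.
#' @export
generate_kww_curve <- function(A = 0.98, tau = 10, beta = 0.6, sigma = 0.01,
                               times = exp(seq(log(0.1), log(200),
                                               length.out = 80)),
                               seed = 1) {
  stopifnot(A > 0, A <= 1, beta > 0, beta <= 1.5, tau > 0)
  C <- A * exp(-(times / tau)^beta)
  if (sigma > 0)
    C <- C + withr::with_seed(seed, rnorm(length(times), sd = sigma))
  out <- tibble(time = times, C = C, n_origins = 1000L)
  class(out) <- c("acf_curve", class(out))
  out
}
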