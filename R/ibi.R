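# Extend an inverted potential beyond its sampled support with a rising
# quadratic wall. Finite-sample histograms end in noisy bins whose local
# slope can even point outward; a simulation then drifts into configurations
# the targets never sampled. The wall keeps it on the sampled support.
# `left`/`right` bound the physically allowed domain (NA = no wall).
harden_potential <- function(pot, left = NA, right = NA, extent, k_wall) {
  g <- pot$grid; U <- pot$U
  h <- stats::median(diff(g))
  wall <- function(d, U0, s0) U0 + pmax(s0, 0) * d + 0.5 * k_wall * d^2
  if (!is.na(left) && g[1] > left + h) {
    d <- seq(h, min(extent, g[1] - left), by = h)
    s0 <- -(U[2] - U[1]) / (g[2] - g[1])      # outward slope at the left edge
    g <- c(g[1] - rev(d), g)
    U <- c(rev(wall(d, U[1], s0)), U)
  }
  n <- length(pot$grid)
  if (!is.na(right) && pot$grid[n] < right - h) {
    d <- seq(h, min(extent, right - pot$grid[n]), by = h)
    s0 <- (pot$U[n] - pot$U[n - 1]) / (pot$grid[n] - pot$grid[n - 1])
    g <- c(g, pot$grid[n] + d)
    U <- c(U, wall(d, pot$U[n], s0))
  }
  tabulated_potential(pot$kind, g, U)
}

harden_set <- function(pots) {
  if (!is.null(pots$bond))
    pots$bond <- harden_potential(pots$bond, left = 1e-3, right = Inf,
                                  extent = 0.15, k_wall = 40000)
  if (!is.null(pots$angle))
    pots$angle <- harden_potential(pots$angle, left = 0, right = 180,
                                   extent = 25, k_wall = 0.5)
  if (!is.null(pots$nonbonded))
    pots$nonbonded <- harden_potential(pots$nonbonded, left = 1e-3, right = NA,
                                       extent = 0.12, k_wall = 20000)
  pots
}

#' Direct Boltzmann inversion of target distributions
#'
#' Converts the four target distributions into initial potential estimates:
#' \deqn{U_{bond}(r) = -k_B T \ln[P(r)/r^2]}
#' \deqn{U_{angle}(\theta) = -k_B T \ln[P(\theta)/\sin\theta]}
#' \deqn{U_{dih}(\phi) = -k_B T \ln P(\phi)}
#' \deqn{U_{nb}(r) = -k_B T \ln g(r)}
#' Bins whose density falls below `floor` are dropped from the sampled
#' support (the engine extends potentials beyond it by linear extrapolation
#' of the boundary slope). Bonded potentials are shifted so their minimum is
#' zero; the nonbonded potential is shifted to zero at its outermost sampled
#' point (the cutoff), keeping the plain-cutoff convention exact.
#'
#' The engine applies torsions in the combined bending-torsion form
#' `T(phi) sin^3(theta1) sin^3(theta2)`; the inversion therefore divides the
#' raw dihedral estimate by the mean bending attenuation
#' `<sin^3 theta>^2` measured from the angle target, so the applied torsion
#' amplitude matches the observed free-energy amplitude from the start.
#'
#' @param targets a [distribution_set()].
#' @param temperature temperature in K; defaults to the set's.
#' @param floor density floor below which bins are excluded before the log.
#' @return a [potential_set()].
#' @export
direct_boltzmann_inversion <- function(targets, temperature = NULL,
                                       floor = 1e-8) {
  stopifnot(inherits(targets, "distribution_set"))
  if (is.null(temperature)) temperature <- targets$temperature
  kT <- kB * temperature
  inv <- function(h, jacobian, kind, shift = c("min", "tail")) {
    shift <- match.arg(shift)
    if (is.null(h) || !nrow(h)) stop("empty target distribution for ", kind)
    keep <- h$density > floor & jacobian > 0
    if (!any(keep)) stop("target distribution for ", kind, " has no support")
    x <- h$x[keep]
    U <- -kT * log(h$density[keep] / jacobian[keep])
    U <- if (shift == "min") U - min(U) else U - U[length(U)]
    tabulated_potential(kind, x, U)
  }
  bond <- inv(targets$bond, targets$bond$x^2, "bond")
  ang <- inv(targets$angle, sin(targets$angle$x * pi / 180), "angle")
  dih <- inv(targets$dihedral, rep(1, nrow(targets$dihedral)), "dihedral")
  gain <- cbt_gain(targets)
  dih <- tabulated_potential("dihedral", dih$grid, dih$U * gain)
  nb <- inv(targets$rdf, rep(1, nrow(targets$rdf)), "nonbonded", shift = "tail")
  harden_set(potential_set(bond, ang, dih, nb, temperature = temperature))
}

# torsion response attenuation of the combined bending-torsion convention:
# 1 / <sin^3 theta>^2 under the target angle distribution, bounded to avoid
# noise amplification
cbt_gain <- function(targets) {
  h <- targets$angle
  w <- diff(hist_breaks(h))
  s3 <- sum(h$density * sin(h$x * pi / 180)^3 * w) / sum(h$density * w)
  min(8, max(1, 1 / s3^2))
}

#' One Iterative Boltzmann Inversion potential update
#'
#' \deqn{U'(x) = U(x) + \alpha\, k_B T \ln[P_{current}(x)/P_{target}(x)]}
#' evaluated where both densities exceed `floor`; elsewhere the correction is
#' extended by constant continuation of the nearest defined value. With
#' `smoothing = "spline"` the correction is smoothed by a cubic smoothing
#' spline before being added — undamped, unsmoothed updates are unstable on
#' noisy finite-sample histograms.
#'
#' @param potential the [tabulated_potential()] being refined.
#' @param current,target [cg_histogram()]s on a common grid.
#' @param temperature K.
#' @param damping update prefactor `alpha` in (0, 1].
#' @param floor density floor.
#' @param smoothing `"spline"` or `"none"`.
#' @param gain response-gain multiplier for the correction (used for the
#'   dihedral under the combined bending-torsion convention, whose response
#'   to a torsion change is attenuated by `<sin^3 theta>^2`).
#' @return the updated [tabulated_potential()].
#' @export
ibi_update <- function(potential, current, target, temperature,
                       damping = 0.2, floor = 1e-8,
                       smoothing = c("spline", "none"), gain = 1) {
  smoothing <- match.arg(smoothing)
  if (damping < 0 || damping > 1) stop("damping must lie in (0, 1]")
  check_common_grid(current, target)
  if (damping == 0) return(potential)
  kT <- kB * temperature
  # update only where both densities are finitely sampled; poorly sampled
  # tail bins (below 1% of the target peak) carry log-ratio noise of order
  # kT and are left to the constant continuation, which adds no force
  well <- pmax(floor, 0.01 * max(target$density))
  ok <- current$density > well & target$density > well &
    current$density > floor & target$density > floor
  if (!any(ok)) return(potential)
  dU <- damping * gain * kT * log(current$density[ok] / target$density[ok])
  dU <- pmin(pmax(dU, -gain * kT), gain * kT)   # per-iteration correction cap
  x_ok <- current$x[ok]
  if (smoothing == "spline" && sum(ok) > 10) {
    fit <- stats::smooth.spline(x_ok, dU, df = max(5, min(sum(ok) %/% 3, 25)))
    dU <- predict(fit, x_ok)$y
  }
  corr <- approx(x_ok, dU, xout = potential$grid, rule = 2)$y
  tabulated_potential(potential$kind, potential$grid, potential$U + corr)
}

check_common_grid <- function(a, b) {
  ba <- hist_breaks(a); bb <- hist_breaks(b)
  if (length(ba) != length(bb) || max(abs(ba - bb)) > 1e-9)
    stop("histograms are not on a common grid")
  invisible(TRUE)
}

#' Convergence norm between a current and a target distribution
#'
#' Both densities are scaled by the factor that unit-normalizes the target;
#' the norm is then the integral of their absolute difference,
#' `norm = s * sum |P_cur - P_tgt| dx` with `s = 1 / integral(P_tgt)`. For a
#' pair of unit-normalized densities this is the total-variation distance
#' scaled to the range `[0, 2]`.
#'
#' @param current,target [cg_histogram()]s on a common grid.
#' @return a nonnegative scalar.
#' @export
convergence_norm <- function(current, target) {
  check_common_grid(current, target)
  w <- diff(hist_breaks(target))
  tot <- sum(target$density * w)
  if (tot <= 0) stop("target distribution has zero integral")
  sum(abs(current$density - target$density) * w) / tot
}

#' @rdname convergence_norm
#' @param norms numeric vector (or list) of per-contribution norms.
#' @export
mean_norm <- function(norms) mean(as.numeric(unlist(norms)))

# norms of every contribution of a measured set against the targets
all_norms <- function(current_set, target_set) {
  vapply(c("bond", "angle", "dihedral", "rdf"), function(k)
    convergence_norm(current_set[[k]], target_set[[k]]), numeric(1))
}

#' Linear-tail pressure correction of the nonbonded potential
#'
#' Adds `dU(r) = A (1 - r/r_cut)` for `r <= r_cut` with
#' `|A| = strength * k_B T` and `sign(A) = sign(measured - target)`: an
#' overpressured system receives a weak attractive tail (positive `dU` at
#' contact decaying to zero at the cutoff lowers the virial pressure), and
#' vice versa. The potential is re-shifted to zero at the cutoff.
#'
#' @param nonbonded the nonbonded [tabulated_potential()].
#' @param measured_P,target_P pressures in bar.
#' @param r_cut cutoff, nm (must be inside the table range).
#' @param strength correction amplitude in units of `k_B T`.
#' @param temperature K.
#' @export
pressure_correction <- function(nonbonded, measured_P, target_P, r_cut,
                                strength = 0.1, temperature = 500) {
  if (r_cut < min(nonbonded$grid) || r_cut > max(nonbonded$grid) + 1e-9)
    stop("r_cut outside the table range")
  A <- sign(measured_P - target_P) * strength * kB * temperature
  dU <- ifelse(nonbonded$grid <= r_cut, A * (1 - nonbonded$grid / r_cut), 0)
  U <- nonbonded$U + dU
  U <- U - approx(nonbonded$grid, U, xout = r_cut, rule = 2)$y
  tabulated_potential("nonbonded", nonbonded$grid, U)
}

#' Engine configuration for IBI iterations
#'
#' Defaults mirror the reference melt conditions: 500 K, 5 fs time step,
#' 1.5 nm cutoff. `n_steps` is the sampled run length per iteration
#' (desk-scale default 20 000 steps; `max_steps` is the hard configuration
#' ceiling of 1 500 000 steps), `equil_steps` are discarded before sampling.
#'
#' @param temperature K.
#' @param dt ps.
#' @param n_steps sampled steps per IBI iteration.
#' @param equil_steps discarded steps per iteration.
#' @param sample_stride steps between sampled frames.
#' @param friction Langevin friction, 1/ps.
#' @param rcut,skin nonbonded cutoff and neighbor skin, nm.
#' @param density initial melt mass density, kg/m^3.
#' @param bond_length initial bond length, nm.
#' @param seed engine seed.
#' @param max_steps configuration ceiling on `n_steps + equil_steps`.
#' @export
ibi_engine_config <- function(temperature = 500, dt = 0.005, n_steps = 20000,
                              equil_steps = 4000, sample_stride = 100,
                              friction = 5, rcut = 1.5, skin = 0.3,
                              density = 930, bond_length = 0.66, seed = 1,
                              max_steps = 1500000) {
  if (n_steps + equil_steps > max_steps)
    stop("n_steps + equil_steps exceeds the configured ceiling")
  list(temperature = temperature, dt = dt, n_steps = as.integer(n_steps),
       equil_steps = as.integer(equil_steps),
       sample_stride = as.integer(sample_stride), friction = friction,
       rcut = rcut, skin = skin, density = density, bond_length = bond_length,
       seed = seed, max_steps = max_steps)
}

#' Tuning schedule for the IBI loop
#'
#' The refinement is staged: (1) direct inversion (or supplied starting
#' potentials), (2) sequential per-contribution cycles in the order
#' bond, angle, dihedral, nonbonded with at most `max_iter` iterations each,
#' (3) `simultaneous_iters` iterations updating all contributions at once,
#' (4) `pressure_iters` pressure-correction iterations. The loop stops as
#' soon as the mean norm falls below `tolerance` or its relative improvement
#' between successive evaluations falls below `improvement_pct` percent.
#'
#' @param max_cycles sequential-stage cycle cap.
#' @param max_iter iteration cap per contribution within a cycle (default 20).
#' @param damping IBI update prefactor.
#' @param tolerance mean-norm stopping threshold.
#' @param improvement_pct relative-improvement stopping threshold, percent.
#' @param simultaneous_iters iterations of the all-contributions stage.
#' @param pressure_iters pressure-correction iterations.
#' @param pressure_target bar.
#' @param pressure_strength correction amplitude in `k_B T`.
#' @param smoothing `"spline"` or `"none"` update smoothing.
#' @param initial_potentials optional [potential_set()] replacing stage 1.
#' @param floor density floor for logs.
#' @export
ibi_schedule <- function(max_cycles = 10, max_iter = 20, damping = 0.2,
                         tolerance = 0.02, improvement_pct = 1,
                         simultaneous_iters = 0, pressure_iters = 0,
                         pressure_target = 1, pressure_strength = 0.1,
                         smoothing = "spline", initial_potentials = NULL,
                         floor = 1e-8) {
  list(max_cycles = max_cycles, max_iter = max_iter, damping = damping,
       tolerance = tolerance, improvement_pct = improvement_pct,
       simultaneous_iters = simultaneous_iters, pressure_iters = pressure_iters,
       pressure_target = pressure_target, pressure_strength = pressure_strength,
       smoothing = smoothing, initial_potentials = initial_potentials,
       floor = floor)
}

#' Run the full Iterative Boltzmann Inversion
#'
#' Derives CG effective potentials whose simulated melt reproduces the four
#' target distributions. Every iteration simulates the melt with the current
#' potentials (warm-starting from the previous final state), measures the
#' four distributions on the target grids, records per-contribution norms,
#' and applies the IBI update of the stage's contribution(s).
#'
#' @param targets a [distribution_set()].
#' @param topology bead-level `system_topology`.
#' @param engine_config from [ibi_engine_config()].
#' @param schedule from [ibi_schedule()].
#' @param initial_state optional [engine_state()] to start from; otherwise a
#'   fresh melt is built at `engine_config$density` and minimized.
#' @param run_dir optional directory for the norm log (CSV) and a final
#'   key-value summary.
#' @param verbose print per-iteration norms.
#' @return list with `potentials` (the refined [potential_set()]), `state`
#'   (an `ibi_state` with the full norm/pressure history) and `final_state`
#'   (the last [engine_state()]).
#' @export
run_ibi <- function(targets, topology, engine_config = ibi_engine_config(),
                    schedule = ibi_schedule(), initial_state = NULL,
                    run_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(targets, "distribution_set"))
  Tk <- engine_config$temperature
  potentials <- schedule$initial_potentials
  if (is.null(potentials))
    potentials <- direct_boltzmann_inversion(targets, Tk, floor = schedule$floor)

  state <- initial_state
  fresh_state <- is.null(state)      # only fresh random configs need minimizing
  if (fresh_state) {
    state <- build_melt_configuration(topology, density = engine_config$density,
                                      bond_length = engine_config$bond_length,
                                      seed = engine_config$seed)
    state <- thermalize_velocities(state, Tk, seed = engine_config$seed)
  }

  log <- list()
  iter_count <- 0L
  sim_seed <- engine_config$seed

  simulate_measure <- function(state, potentials, extra_equil = 0) {
    sim_seed <<- sim_seed + 1
    eq <- engine_config$equil_steps + extra_equil
    if (eq > 0) {
      r0 <- run_md(state, potentials, topology, n_steps = eq,
                   dt = engine_config$dt, temperature = Tk,
                   friction = engine_config$friction, seed = sim_seed,
                   obs_stride = max(1L, eq), traj_stride = 0L,
                   min_steps = if (iter_count == 0L && fresh_state) 500L else 0L,
                   rcut = engine_config$rcut, skin = engine_config$skin)
      state <- r0$state
    }
    r <- run_md(state, potentials, topology, n_steps = engine_config$n_steps,
                dt = engine_config$dt, temperature = Tk,
                friction = engine_config$friction, seed = sim_seed + 1e6,
                obs_stride = 50L, traj_stride = engine_config$sample_stride,
                rcut = engine_config$rcut, skin = engine_config$skin)
    current <- measure_distributions(r$trajectory, template = targets,
                                     temperature = Tk)
    list(state = r$state, current = current,
         pressure = mean(r$observables$pressure),
         norms = all_norms(current, targets))
  }

  record <- function(stage, cycle, contribution, norms, pressure) {
    iter_count <<- iter_count + 1L
    log[[iter_count]] <<- tibble(
      iteration = iter_count, stage = stage, cycle = cycle,
      contribution = contribution,
      norm_bond = norms[["bond"]], norm_angle = norms[["angle"]],
      norm_dihedral = norms[["dihedral"]], norm_rdf = norms[["rdf"]],
      mean_norm = mean_norm(norms), pressure = pressure)
    if (verbose)
      message(sprintf("[%s c%s %s] mean norm %.4f", stage, cycle, contribution,
                      mean_norm(norms)))
  }

  pot_slot <- c(bond = "bond", angle = "angle", dihedral = "dihedral",
                rdf = "nonbonded")
  upd_gain <- c(bond = 1, angle = 1, dihedral = cbt_gain(targets), rdf = 1)

  # initial evaluation: the fixed point of the loop costs zero refinements
  ev <- simulate_measure(state, potentials)
  state <- ev$state
  record("initial", 0L, "none", ev$norms, ev$pressure)
  best <- mean_norm(ev$norms)
  refinements <- 0L
  converged <- best < schedule$tolerance

  if (!converged) {
    prev_cycle_norm <- best
    for (cycle in seq_len(schedule$max_cycles)) {
      for (contrib in c("bond", "angle", "dihedral", "rdf")) {
        # a contribution already at tolerance needs no tuning this cycle
        if (ev$norms[[contrib]] < schedule$tolerance) next
        for (it in seq_len(schedule$max_iter)) {
          n_before <- ev$norms[[contrib]]
          slot <- pot_slot[[contrib]]
          potentials[[slot]] <- ibi_update(
            potentials[[slot]], ev$current[[contrib]], targets[[contrib]],
            Tk, damping = schedule$damping, floor = schedule$floor,
            smoothing = schedule$smoothing, gain = upd_gain[[contrib]])
          refinements <- refinements + 1L
          ev <- simulate_measure(state, potentials)
          state <- ev$state
          record("sequential", cycle, contrib, ev$norms, ev$pressure)
          if (mean_norm(ev$norms) < schedule$tolerance) break
          improv <- (n_before - ev$norms[[contrib]]) / max(n_before, 1e-12)
          if (ev$norms[[contrib]] < schedule$tolerance ||
              improv < schedule$improvement_pct / 100) break
        }
        if (mean_norm(ev$norms) < schedule$tolerance) break
      }
      mn <- mean_norm(ev$norms)
      if (mn < schedule$tolerance) { converged <- TRUE; break }
      if ((prev_cycle_norm - mn) / max(prev_cycle_norm, 1e-12) <
          schedule$improvement_pct / 100) break
      prev_cycle_norm <- mn
    }
  }

  # stage 3: simultaneous tuning of all contributions
  if (!converged && schedule$simultaneous_iters > 0) {
    for (it in seq_len(schedule$simultaneous_iters)) {
      for (contrib in c("bond", "angle", "dihedral", "rdf")) {
        slot <- pot_slot[[contrib]]
        potentials[[slot]] <- ibi_update(
          potentials[[slot]], ev$current[[contrib]], targets[[contrib]],
          Tk, damping = schedule$damping, floor = schedule$floor,
          smoothing = schedule$smoothing, gain = upd_gain[[contrib]])
      }
      refinements <- refinements + 1L
      ev <- simulate_measure(state, potentials)
      state <- ev$state
      record("simultaneous", NA_integer_, "all", ev$norms, ev$pressure)
      if (mean_norm(ev$norms) < schedule$tolerance) { converged <- TRUE; break }
    }
  }

  # stage 4: pressure correction
  if (schedule$pressure_iters > 0) {
    for (it in seq_len(schedule$pressure_iters)) {
      potentials$nonbonded <- pressure_correction(
        potentials$nonbonded, ev$pressure, schedule$pressure_target,
        r_cut = engine_config$rcut, strength = schedule$pressure_strength,
        temperature = Tk)
      refinements <- refinements + 1L
      ev <- simulate_measure(state, potentials)
      state <- ev$state
      record("pressure", NA_integer_, "nonbonded", ev$norms, ev$pressure)
      if (abs(ev$pressure - schedule$pressure_target) <
          0.05 * abs(schedule$pressure_target)) break
    }
  }

  log_tbl <- dplyr::bind_rows(log)
  ibi_state <- structure(
    list(log = log_tbl, n_iterations = iter_count, refinements = refinements,
         converged = converged || mean_norm(ev$norms) < schedule$tolerance,
         mean_norm = mean_norm(ev$norms), final_norms = ev$norms,
         pressure = ev$pressure),
    class = "ibi_state")

  if (!is.null(run_dir)) {
    dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(log_tbl, file.path(run_dir, "norms.csv"), row.names = FALSE)
    write_potential_set(potentials, file.path(run_dir, "potentials"))
    writeLines(c(
      sprintf("converged %s", ibi_state$converged),
      sprintf("mean_norm %.6f", ibi_state$mean_norm),
      sprintf("refinements %d", refinements),
      sprintf("iterations %d", iter_count),
      sprintf("pressure_bar %.4f", ev$pressure)),
      file.path(run_dir, "summary.txt"))
  }

  list(potentials = potentials, state = ibi_state, final_state = state)
}

#' @export
print.ibi_state <- function(x, ...) {
  cat(sprintf("ibi_state: %d evaluations, %d refinements, mean norm %.4f (%s)\n",
              x$n_iterations, x$refinements, x$mean_norm,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
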