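# positions of one frame arranged chain-major with a fixed per-chain particle
# count; optionally restricted to backbone atoms
chain_major_positions <- function(fr, topology, level = c("monomer", "backbone")) {
  level <- match.arg(level)
  if (level == "monomer") return(fr$positions)
  keep <- topology$atoms$backbone
  fr$positions[keep, , drop = FALSE]
}

particles_per_chain <- function(topology, level) {
  if (level == "monomer") topology$N
  else sum(topology$atoms$backbone & topology$atoms$chain == 1L)
}

# resolve any supported trajectory/topology pairing to chain-major frames
resolve_level <- function(traj, topology = NULL, level = NULL) {
  if (is.null(topology)) topology <- traj$topology
  if (is.null(topology)) stop("a topology is required")
  if (is.null(level))
    level <- if (topology$level == "cg" || inherits(traj, "cg_trajectory"))
      "monomer" else "backbone"
  if (level == "backbone" && !any(topology$atoms$backbone))
    stop("backbone flags are required for backbone-level analysis")
  list(topology = topology, level = level,
       npc = particles_per_chain(topology, level))
}

#' Mean squared internal distances along the chain
#'
#' `<R_n^2>/n` as a function of the index separation `n`, averaged over all
#' index pairs at that separation, all chains and all frames. At
#' `level = "monomer"` the separation counts monomers (CG beads); at
#' `level = "backbone"` it counts backbone atoms, giving separations up to
#' `7N - 1` for the PCL template. Frames must hold contiguous (unwrapped)
#' molecules.
#'
#' @param traj a [trajectory()] (unwrapped) or `cg_trajectory`.
#' @param topology a `system_topology`; taken from the trajectory if present.
#' @param level `"monomer"` or `"backbone"` (`"backbone-atom"` is accepted).
#' @return an `internal_distance_profile` tibble with columns `n`, `msd`
#'   (`<R_n^2>`, nm^2) and `ratio` (`<R_n^2>/n`).
#' @export
internal_distances <- function(traj, topology = NULL, level = NULL) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  if (!is.null(level) && level == "backbone-atom") level <- "backbone"
  rl <- resolve_level(traj, topology, level)
  npc <- rl$npc
  if (npc < 2) stop("chains need at least 2 particles at this level")
  sumsq <- numeric(npc - 1); cnt <- numeric(npc - 1)
  for (fr in traj$frames) {
    p <- chain_major_positions(fr, rl$topology, rl$level)
    acc <- cpp_internal_profile(p, rl$topology$n_chains, npc)
    sumsq <- sumsq + acc$sumsq; cnt <- cnt + acc$count
  }
  out <- tibble(n = seq_len(npc - 1), msd = sumsq / cnt,
                ratio = sumsq / cnt / seq_len(npc - 1))
  attr(out, "level") <- rl$level
  class(out) <- c("internal_distance_profile", class(out))
  out
}

#' Characteristic ratio of the chain backbone
#'
#' `C_n = <R_n^2> / (n b^2)` with `b` the root-mean-square consecutive
#' backbone-atom distance measured from the same data (so `C_1 = 1` by
#' construction), for separations up to the backbone length minus one
#' (`7N - 1` for the PCL template). The long-chain plateau `C_inf` is
#' estimated as the mean of `C_n` over the top decile of `n` — a reproducible
#' stand-in for reading the plateau off a plot.
#'
#' @inheritParams internal_distances
#' @param level index level; defaults to `"backbone"` for atomistic
#'   topologies and `"monomer"` for CG ones.
#' @return a `characteristic_ratio` object: tibble (`n`, `C_n`) with
#'   attributes `b` (nm) and `C_inf`.
#' @export
characteristic_ratio <- function(traj, topology = NULL, level = NULL) {
  prof <- internal_distances(traj, topology, level)
  b2 <- prof$msd[1]                      # mean squared consecutive distance
  out <- tibble(n = prof$n, C_n = prof$msd / (prof$n * b2))
  top <- out$C_n[out$n > max(out$n) * 0.9]
  attr(out, "b") <- sqrt(b2)
  attr(out, "C_inf") <- mean(top)
  class(out) <- c("characteristic_ratio", class(out))
  out
}

#' Gyration-tensor shape analysis of one chain
#'
#' The geometric (unweighted) gyration tensor in its double-sum form,
#' \deqn{T_{\alpha\beta} = \frac{1}{2N_p^2}\sum_i\sum_j
#'   (r_{i\alpha}-r_{j\alpha})(r_{i\beta}-r_{j\beta}),}
#' which is algebraically identical to the centered single-sum second-moment
#' tensor. Its sorted eigenvalues give the squared radius of gyration
#' (`Rg2 = lambda1 + lambda2 + lambda3`) and the asphericity
#' \deqn{a = \frac{(\lambda_2-\lambda_1)^2 + (\lambda_3-\lambda_1)^2 +
#'   (\lambda_3-\lambda_2)^2}{2(\lambda_1+\lambda_2+\lambda_3)^2},}
#' 0 for spherically symmetric clouds and 1 for rods. The end-to-end
#' distance is taken between the first and last particle.
#'
#' @param positions `n x 3` matrix of one chain's particle positions
#'   (contiguous, unwrapped), nm.
#' @return a `gyration_result`: list with `tensor`, `eigenvalues`
#'   (ascending), `Rg2`, `asphericity`, `Re`.
#' @export
gyration_analysis <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("at least 2 particles are required")
  centered <- sweep(positions, 2, colMeans(positions))
  T_ab <- crossprod(centered) / nrow(positions)
  ev <- sort(eigen(T_ab, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0] <- 0
  tr <- sum(ev)
  if (tr <= 0) stop("all particles coincident: asphericity undefined")
  a <- ((ev[2] - ev[1])^2 + (ev[3] - ev[1])^2 + (ev[3] - ev[2])^2) / (2 * tr^2)
  Re <- sqrt(sum((positions[nrow(positions), ] - positions[1, ])^2))
  structure(list(tensor = T_ab, eigenvalues = ev, Rg2 = tr, asphericity = a,
                 Re = Re), class = "gyration_result")
}

#' Per-chain shape table for a trajectory
#'
#' Runs [gyration_analysis()] on every chain in every frame.
#'
#' @inheritParams internal_distances
#' @return a tibble with columns `frame`, `chain`, `Rg2`, `asphericity`, `Re`.
#' @export
chain_shapes <- function(traj, topology = NULL, level = NULL) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  rl <- resolve_level(traj, topology, level)
  npc <- rl$npc
  rows <- lapply(seq_along(traj$frames), function(fi) {
    p <- chain_major_positions(traj$frames[[fi]], rl$topology, rl$level)
    g <- lapply(seq_len(rl$topology$n_chains), function(c) {
      idx <- ((c - 1) * npc + 1):(c * npc)
      gr <- gyration_analysis(p[idx, , drop = FALSE])
      tibble(frame = fi, chain = c, Rg2 = gr$Rg2,
             asphericity = gr$asphericity, Re = gr$Re)
    })
    dplyr::bind_rows(g)
  })
  dplyr::bind_rows(rows)
}

#' Single-chain form factor (Debye sum)
#'
#' Isotropically averaged scattering function of one molecule,
#' `W(q) = (1/Np) < sum_jk sin(q r_jk)/(q r_jk) >`, returned normalized per
#' particle (`W(q)/Np`, which tends to 1 as `q -> 0`). The fractal exponent
#' `nu` is fitted as `-1/slope` of `log W` vs `log q` restricted to the
#' intermediate regime `1/Rg <= q <= 1/b`, with `Rg` and the mean bond
#' length `b` measured from the same data. Because that window spans only
#' about one decade for chains of a few hundred particles, the fit includes
#' a `1/q^2` correction-to-scaling regressor that absorbs the Guinier
#' shoulder; without it the slope of an ideal chain's exact scattering curve
#' would be biased well away from its asymptotic exponent.
#'
#' @inheritParams internal_distances
#' @param q wave-vector grid, 1/nm; must be positive (the `q -> 0` limit is
#'   the analytic value 1).
#' @return a `form_factor_curve` tibble (`q`, `W`) with attributes `nu`,
#'   `fit_range`, `Rg`, `b`.
#' @export
form_factor <- function(traj, topology = NULL, q = NULL, level = NULL) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  rl <- resolve_level(traj, topology, level)
  npc <- rl$npc
  Rg <- b <- NA_real_
  if (npc >= 2) {
    # mean Rg and bond length for the fit window
    sh <- chain_shapes(traj, rl$topology, rl$level)
    Rg <- sqrt(mean(sh$Rg2))
    b <- mean_bond_length(traj, rl$topology, rl$level)
  }
  if (is.null(q)) {
    if (npc < 2) stop("an explicit q grid is required for single-particle chains")
    q <- exp(seq(log(0.5 / Rg), log(2 / b), length.out = 48))
  }
  if (any(q <= 0)) stop("q must be positive; use the analytic limit W/Np = 1 at q = 0")
  W <- numeric(length(q))
  for (fr in traj$frames) {
    p <- chain_major_positions(fr, rl$topology, rl$level)
    W <- W + cpp_debye(p, rl$topology$n_chains, npc, q)
  }
  W <- W / length(traj$frames)
  out <- tibble(q = q, W = W)
  inwin <- !is.na(Rg) & q >= 1 / Rg & q <= 1 / b
  nu <- NA_real_
  if (sum(inwin) >= 4) {
    # fractal exponent with a 1/q^2 correction-to-scaling regressor: for
    # finite chains the window reaches only one decade and the Guinier
    # shoulder otherwise biases the slope
    qw <- q[inwin]
    fit <- lm(log(W[inwin]) ~ log(qw) + I(1 / qw^2))
    nu <- -1 / unname(coef(fit)[2])
  }
  attr(out, "nu") <- nu
  attr(out, "fit_range") <- c(1 / Rg, 1 / b)
  attr(out, "Rg") <- Rg
  attr(out, "b") <- b
  class(out) <- c("form_factor_curve", class(out))
  out
}

mean_bond_length <- function(traj, topology, level) {
  npc <- particles_per_chain(topology, level)
  tot <- 0; cnt <- 0
  for (fr in traj$frames) {
    p <- chain_major_positions(fr, topology, level)
    idx <- seq_len(nrow(p))
    same_chain <- (idx[-1] - 1) %/% npc == (idx[-length(idx)] - 1) %/% npc
    d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    tot <- tot + sum(sqrt(rowSums(d^2))[same_chain])
    cnt <- cnt + sum(same_chain)
  }
  tot / cnt
}

#' Scaling exponent from a size-vs-N power-law fit
#'
#' Least-squares slope of `log(size)` against `log(N)`; 0.5 for ideal melts
#' (`Rg ~ N^0.5`).
#'
#' @param sizes chain sizes (e.g. `Rg`), positive.
#' @param N chain lengths, positive; at least 3 points.
#' @export
scaling_fit <- function(sizes, N) {
  if (length(sizes) != length(N) || length(N) < 3)
    stop("at least 3 (size, N) points are required")
  if (any(sizes <= 0) || any(N <= 0)) stop("sizes and N must be positive")
  unname(coef(lm(log(sizes) ~ log(N)))[2])
}

#' Packing length of a melt
#'
#' `p = M_w / (<Re^2> rho N_A)` converted to nm, with `M_w` the chain molar
#' mass (g/mol), `<Re^2>` the mean squared end-to-end distance (nm^2) and
#' `rho` the melt mass density (kg/m^3). For ideal melts `p` is independent
#' of chain length.
#'
#' @param M_w chain molar mass, g/mol.
#' @param Re2 mean squared end-to-end distance, nm^2.
#' @param rho melt density, kg/m^3.
#' @return packing length in nm.
#' @export
packing_length <- function(M_w, Re2, rho) {
  if (any(c(M_w, Re2) <= 0)) stop("M_w and Re2 must be positive")
  if (rho <= 0) stop("density must be positive")
  (M_w * 1e-3) / (Re2 * 1e-18 * rho * N_AVOGADRO) * 1e9
}

#' Entanglement estimates from the packing length
#'
#' `M_e = n_t^2 rho N_A p^3` (g/mol) with the universal packing number
#' `n_t ~ 21`; the beads per entanglement strand `N_e = round(M_e / M_mono)`;
#' the critical mass `M_c = 2 M_e`; and the entanglement-onset chain length
#' `2 N_e` monomers.
#'
#' @param p packing length, nm.
#' @param rho melt density, kg/m^3.
#' @param n_t dimensionless packing number (default 21).
#' @param monomer_mass monomer molar mass, g/mol (default: caprolactone,
#'   114.14 g/mol).
#' @return an `entanglement_estimate`: list with `p`, `rho`, `n_t`, `M_e`,
#'   `N_e`, `M_c`, `onset_N`.
#' @export
entanglement_estimates <- function(p, rho, n_t = 21,
                                   monomer_mass = MONOMER_MASS_PCL) {
  if (any(c(p, rho, n_t, monomer_mass) <= 0)) stop("all inputs must be positive")
  M_e <- n_t^2 * rho * N_AVOGADRO * (p * 1e-9)^3 * 1e3   # g/mol
  N_e <- round(M_e / monomer_mass)
  structure(list(p = p, rho = rho, n_t = n_t, M_e = M_e, N_e = N_e,
                 M_c = 2 * M_e, onset_N = 2 * N_e),
            class = "entanglement_estimate")
}

#' @export
print.entanglement_estimate <- function(x, ...) {
  cat(sprintf("entanglement_estimate: p = %.3f nm, M_e = %.0f g/mol, N_e = %d, M_c = %.0f g/mol, onset N = %d\n",
              x$p, x$M_e, x$N_e, x$M_c, x$onset_N))
  invisible(x)
}
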