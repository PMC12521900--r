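#' Unwrap molecules across periodic boundaries
#'
#' Makes every molecule spatially contiguous by walking along each chain's
#' particles in order and shifting each to the minimum image of its
#' predecessor. Centers of mass across a periodic seam are otherwise
#' ill-defined, so mapping always unwraps first.
#'
#' @param fr a [frame()].
#' @param topology a `system_topology`; particle order must be chain-major.
#' @return an unwrapped [frame()].
#' @export
unwrap_molecules <- function(fr, topology) {
  pos <- fr$positions
  if (nrow(pos) != n_particles(topology))
    stop("frame particle count does not match topology")
  box <- fr$box
  chain <- topology$atoms$chain
  d <- diff(pos)                       # consecutive-particle deltas
  new_chain <- diff(chain) != 0
  shift <- -sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  shift[new_chain, ] <- 0              # chain starts anchor themselves
  pos_out <- pos
  pos_out[-1, ] <- pos[-1, ] + apply_cum_shift(shift, new_chain)
  # a molecule is broken if any within-chain consecutive distance still
  # exceeds half the smallest box edge
  dd <- diff(pos_out)[!new_chain, , drop = FALSE]
  if (length(dd) && max(sqrt(rowSums(dd^2))) > min(box) / 2)
    stop("broken molecule: bond longer than half the smallest box edge after unwrapping")
  frame(pos_out, box, fr$time)
}

# cumulative sum of per-step shifts, restarting at each chain boundary
apply_cum_shift <- function(shift, new_chain) {
  grp <- cumsum(c(TRUE, new_chain))[seq_len(nrow(shift))]
  # cumulative within groups, vectorized via ave per column
  out <- shift
  for (k in 1:3) out[, k] <- stats::ave(shift[, k], grp, FUN = cumsum)
  out
}

#' @rdname unwrap_molecules
#' @param traj a [trajectory()].
#' @export
unwrap_trajectory <- function(traj, topology) {
  traj$frames <- lapply(traj$frames, unwrap_molecules, topology = topology)
  traj
}

#' Map a fine-grained trajectory to one bead per monomer
#'
#' Places each bead at the mass-weighted center of its monomer's atoms,
#' computed on unwrapped molecules. Bead mass is the summed member mass, so
#' total mass and the system's mass-weighted center are preserved frame by
#' frame.
#'
#' @param traj a [trajectory()] at the topology's atomistic resolution.
#' @param topology a `system_topology` with a complete bead assignment.
#' @param unwrap unwrap molecules before taking centers of mass.
#' @return a `cg_trajectory`: a [trajectory()] of bead positions carrying the
#'   parent topology and a bead-level topology.
#' @export
map_to_beads <- function(traj, topology, unwrap = TRUE) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  nb <- n_beads(topology)
  assign <- topology$bead_of_atom
  if (length(assign) != n_particles(topology) || anyNA(assign))
    stop("topology bead assignment must cover all atoms")
  m <- topology$atoms$mass
  wsum <- as.vector(tapply(m, assign, sum))
  if (any(wsum <= 0)) stop("every bead needs positive total mass")

  cg_frames <- lapply(traj$frames, function(fr) {
    if (unwrap) fr <- unwrap_molecules(fr, topology)
    p <- fr$positions
    com <- matrix(NA_real_, nb, 3)
    for (k in 1:3)
      com[, k] <- as.vector(tapply(m * p[, k], assign, sum)) / wsum
    frame(com, fr$box, fr$time)
  })
  out <- trajectory(cg_frames)
  out$parent_topology <- topology
  out$topology <- bead_topology_of(topology)
  class(out) <- c("cg_trajectory", class(out))
  out
}

# CG-level topology whose bead masses are the mapped monomer masses
bead_topology_of <- function(topology) {
  if (topology$level == "cg") return(topology)
  bm <- bead_masses(topology)
  atoms <- tibble(
    chain = bead_chain(topology), monomer = bead_index(topology),
    mass = bm, backbone = TRUE, label = "B")
  system_topology(atoms, topology$n_chains, topology$N,
                  molar_mass_chain = topology$molar_mass_chain, level = "cg")
}

# attach a CG topology to a plain trajectory (e.g. engine output)
as_cg_trajectory <- function(traj, topology) {
  traj$topology <- if (topology$level == "cg") topology else bead_topology_of(topology)
  if (!inherits(traj, "cg_trajectory"))
    class(traj) <- c("cg_trajectory", class(traj))
  traj
}
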