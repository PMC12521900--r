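#' Build a polymer system topology
#'
#' A `system_topology` describes `n_chains` identical linear chains of `N`
#' monomers each, with one coarse-grained bead per monomer. The `atoms` table
#' lists every particle (atomistic or bead-level) with its chain, monomer,
#' mass, backbone flag and label; `bead_of_atom` assigns every atom to exactly
#' one bead, bead index `(chain - 1) * N + monomer`.
#'
#' @param atoms a data frame with columns `chain`, `monomer`, `mass`,
#'   `backbone`, `label` (one row per particle, ordered chain-major).
#' @param n_chains number of chains.
#' @param N monomers (beads) per chain.
#' @param molar_mass_chain chain molar mass in g/mol; defaults to the summed
#'   atom masses of the first chain.
#' @param level `"atomistic"` or `"cg"`.
#' @return an object of class `system_topology`.
#' @export
system_topology <- function(atoms, n_chains, N, molar_mass_chain = NULL,
                            level = c("atomistic", "cg")) {
  level <- match.arg(level)
  atoms <- as_tibble(atoms)
  stopifnot(all(c("chain", "monomer", "mass", "backbone", "label") %in% names(atoms)))
  if (any(atoms$monomer < 1L) || any(atoms$monomer > N))
    stop("monomer index outside 1..N")
  if (any(atoms$chain < 1L) || any(atoms$chain > n_chains))
    stop("chain index outside 1..n_chains")
  bead_of_atom <- (atoms$chain - 1L) * N + atoms$monomer
  if (is.null(molar_mass_chain))
    molar_mass_chain <- sum(atoms$mass[atoms$chain == 1L])
  structure(
    list(atoms = atoms, n_chains = as.integer(n_chains), N = as.integer(N),
         bead_of_atom = as.integer(bead_of_atom),
         molar_mass_chain = molar_mass_chain, level = level),
    class = "system_topology")
}

#' @export
print.system_topology <- function(x, ...) {
  cat(sprintf("system_topology (%s): %d chains x %d monomers, %d particles, chain M_w = %.2f g/mol\n",
              x$level, x$n_chains, x$N, nrow(x$atoms), x$molar_mass_chain))
  invisible(x)
}

n_particles <- function(topology) nrow(topology$atoms)
n_beads <- function(topology) topology$n_chains * topology$N

# per-bead chain index and index-within-chain (1-based), chain-major order
bead_chain <- function(topology) rep(seq_len(topology$n_chains), each = topology$N)
bead_index <- function(topology) rep(seq_len(topology$N), times = topology$n_chains)

#' Bead masses of a topology
#'
#' Mass of each bead as the sum of its member atom masses, in chain-major
#' bead order.
#'
#' @param topology a `system_topology`.
#' @export
bead_masses <- function(topology) {
  as.vector(tapply(topology$atoms$mass, topology$bead_of_atom, sum))
}

#' Bead-level (coarse-grained) topology
#'
#' One particle per monomer; used for CG melts where each bead carries the
#' full monomer mass.
#'
#' @param N beads per chain.
#' @param n_chains number of chains.
#' @param bead_mass mass per bead in g/mol (default: the caprolactone repeat
#'   unit, 114.14 g/mol).
#' @return a `system_topology` at `"cg"` level.
#' @export
cg_topology <- function(N, n_chains = 70L, bead_mass = MONOMER_MASS_PCL) {
  atoms <- tibble(
    chain = rep(seq_len(n_chains), each = N),
    monomer = rep(seq_len(N), times = n_chains),
    mass = bead_mass, backbone = TRUE,
    label = "B")
  system_topology(atoms, n_chains, N, level = "cg")
}

#' Poly(epsilon-caprolactone) chain topology template
#'
#' Builds an atomistic-level topology for linear PCL chains with one bead per
#' monomer. Internal monomers carry 18 atoms (the C6H10O2 repeat unit);
#' the two chain ends carry 19 and 20 atoms for the extra end-group atoms.
#' Seven atoms per monomer (six carbons and the ester oxygen) are flagged as
#' backbone, so a chain has `7 N` backbone atoms and a maximum backbone
#' separation of `7 N - 1`.
#'
#' The chain molar mass follows the standard capping-hydrogen convention,
#' `N * 114.144 + 2 * 1.008` g/mol, which reproduces the catalogue values for
#' N = 10, 30, 50, 100, 125 (1143, 3426, 5709, 11416, 14270 g/mol at integer
#' rounding). Note that the end-group *atom counts* (19/20) and the
#' capping-hydrogen *mass* convention are different bookkeeping conventions;
#' the topology follows both deliberately: masses for beads sum to each
#' monomer's chemical mass plus its capping hydrogens.
#'
#' @param N monomers per chain (must be at least 2 so the two ends exist).
#' @param n_chains number of chains (default 70).
#' @return a `system_topology` at `"atomistic"` level.
#' @export
build_pcl_topology <- function(N, n_chains = 70L) {
  if (N < 2) stop("N must be >= 2: a chain needs two distinct terminal monomers")
  mC <- 12.011; mH <- 1.008; mO <- 15.999

  # repeat unit C6H10O2, backbone first: 5 methylene C, carbonyl C, ester O
  base_label <- c(paste0("C", 1:6), "O1", paste0("H", 1:10), "O2")
  base_mass <- c(rep(mC, 6), mO, rep(mH, 10), mO)
  base_backbone <- c(rep(TRUE, 7), rep(FALSE, 11))

  monomer_atoms <- function(mono, N) {
    lab <- base_label; mass <- base_mass; bb <- base_backbone
    if (mono == 1L) {            # 19 atoms: hydroxyl-end hydrogen
      lab <- c(lab, "HO"); mass <- c(mass, mH); bb <- c(bb, FALSE)
    } else if (mono == N) {      # 20 atoms: carboxyl-end atoms
      lab <- c(lab, "HC", "HX"); mass <- c(mass, mH, 0); bb <- c(bb, FALSE, FALSE)
    }
    tibble(monomer = mono, mass = mass, backbone = bb, label = lab)
  }

  per_chain <- dplyr::bind_rows(lapply(seq_len(N), monomer_atoms, N = N))
  atoms <- dplyr::bind_rows(lapply(seq_len(n_chains), function(c) {
    dplyr::mutate(per_chain, chain = c)
  }))
  atoms <- atoms[, c("chain", "monomer", "mass", "backbone", "label")]
  mw <- N * MONOMER_MASS_PCL + 2 * mH
  system_topology(atoms, n_chains, N, molar_mass_chain = mw, level = "atomistic")
}

#' Write / read a topology as a key-value text file
#'
#' Plain-text serialization: header lines `n_chains`, `N`, `molar_mass_chain`,
#' `level`, followed by one whitespace-separated atom record per line for the
#' first chain (all chains are identical).
#'
#' @param topology a `system_topology`.
#' @param path output file.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("n_chains %d", topology$n_chains),
    sprintf("N %d", topology$N),
    sprintf("molar_mass_chain %.6f", topology$molar_mass_chain),
    sprintf("level %s", topology$level),
    "atoms monomer mass backbone label"), con)
  a1 <- topology$atoms[topology$atoms$chain == 1L, ]
  writeLines(sprintf("%d %.6f %d %s", a1$monomer, a1$mass,
                     as.integer(a1$backbone), a1$label), con)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  ln <- readLines(path)
  kv <- function(key) sub(paste0("^", key, " +"), "", ln[grep(paste0("^", key, " "), ln)[1]])
  n_chains <- as.integer(kv("n_chains"))
  N <- as.integer(kv("N"))
  mw <- as.numeric(kv("molar_mass_chain"))
  level <- kv("level")
  hdr <- grep("^atoms ", ln)[1]
  rec <- do.call(rbind, strsplit(ln[(hdr + 1):length(ln)], " +"))
  a1 <- tibble(monomer = as.integer(rec[, 1]), mass = as.numeric(rec[, 2]),
               backbone = as.logical(as.integer(rec[, 3])), label = rec[, 4])
  atoms <- dplyr::bind_rows(lapply(seq_len(n_chains), function(c)
    dplyr::mutate(a1, chain = c)))
  atoms <- atoms[, c("chain", "monomer", "mass", "backbone", "label")]
  system_topology(atoms, n_chains, N, molar_mass_chain = mw,
                  level = if (level == "cg") "cg" else "atomistic")
}
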