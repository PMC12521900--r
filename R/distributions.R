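#' One-dimensional distribution histogram
#'
#' Normalized density histogram used for the coarse-graining targets. For
#' bonded observables the density integrates to one; the radial distribution
#' function is normalized by ideal-gas shell counts instead and tends to one
#' at large distance in a homogeneous melt.
#'
#' @param breaks bin edges (nm or degrees).
#' @param density normalized density per bin.
#' @param n_samples number of samples binned.
#' @param observable one of `"bond"`, `"angle"`, `"dihedral"`, `"rdf"`.
#' @param n_skipped samples skipped as degenerate (coincident/collinear).
#' @return an object of classes `cg_histogram` and `tbl_df` with columns
#'   `x` (bin centers) and `density`, plus metadata attributes.
#' @export
cg_histogram <- function(breaks, density, n_samples, observable, n_skipped = 0L) {
  out <- tibble(x = (head(breaks, -1) + tail(breaks, -1)) / 2,
                density = as.numeric(density))
  attr(out, "breaks") <- breaks
  attr(out, "n_samples") <- n_samples
  attr(out, "observable") <- observable
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("cg_histogram", class(out))
  out
}

hist_breaks <- function(h) attr(h, "breaks")
hist_observable <- function(h) attr(h, "observable")

bin_density <- function(x, breaks) {
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = FALSE),
                  nbins = length(breaks) - 1)
  # findInterval returns 0 below the range; drop those via nbins cap above
  if (sum(cnt) == 0) return(numeric(length(breaks) - 1))
  cnt / (sum(cnt) * diff(breaks))
}

require_cg <- function(cgtraj) {
  if (!inherits(cgtraj, "cg_trajectory") || is.null(cgtraj$topology))
    stop("a cg_trajectory with an attached topology is required")
  if (n_frames(cgtraj) == 0) stop("empty trajectory")
  invisible(cgtraj)
}

# consecutive-bead tuple index matrices (0-based, for the C++ kernels)
bead_tuples <- function(topology, k) {
  N <- topology$N
  if (N < k) return(matrix(integer(0), 0, k))
  starts <- seq_len(N - k + 1)
  one <- vapply(seq_len(k) - 1L, function(j) starts + j, numeric(N - k + 1))
  offs <- (seq_len(topology$n_chains) - 1L) * N
  do.call(rbind, lapply(offs, function(o) one + o)) - 1L
}

#' Bond-length distribution between consecutive beads
#'
#' One sample per consecutive bead pair per frame; the histogram density is
#' normalized to unit integral.
#'
#' @param cgtraj a `cg_trajectory`.
#' @param bin_width bin width, nm.
#' @param breaks explicit bin edges overriding `bin_width` (used to measure
#'   on the same grid as a target histogram).
#' @return a [cg_histogram()].
#' @export
bond_distribution <- function(cgtraj, bin_width = 0.002, breaks = NULL) {
  require_cg(cgtraj)
  topo <- cgtraj$topology
  if (topo$N < 2) stop("at least 2 beads per chain are required")
  pairs <- bead_tuples(topo, 2L)
  vals <- unlist(lapply(cgtraj$frames, function(fr) {
    d <- fr$positions[pairs[, 2] + 1L, , drop = FALSE] -
      fr$positions[pairs[, 1] + 1L, , drop = FALSE]
    d <- d - sweep(round(sweep(d, 2, fr$box, "/")), 2, fr$box, "*")
    sqrt(rowSums(d^2))
  }))
  if (is.null(breaks)) breaks <- pretty_edges(vals, bin_width)
  cg_histogram(breaks, bin_density(vals, breaks), length(vals), "bond")
}

pretty_edges <- function(vals, bin_width) {
  lo <- floor(min(vals) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width + bin_width
  seq(lo, hi, by = bin_width)
}

#' Bending-angle distribution between consecutive bead triples
#'
#' Angles in degrees in `[0, 180]`. Degenerate triples (coincident beads) are
#' skipped and tallied in the `n_skipped` attribute.
#'
#' @inheritParams bond_distribution
#' @param bin_width bin width, degrees.
#' @export
angle_distribution <- function(cgtraj, bin_width = 1, breaks = NULL) {
  require_cg(cgtraj)
  topo <- cgtraj$topology
  if (topo$N < 3) stop("at least 3 beads per chain are required")
  triples <- bead_tuples(topo, 3L)
  vals <- unlist(lapply(cgtraj$frames, function(fr)
    cpp_angles(fr$positions, fr$box, triples)))
  skipped <- sum(is.na(vals)); vals <- vals[!is.na(vals)]
  if (is.null(breaks)) breaks <- seq(0, 180, by = bin_width)
  cg_histogram(breaks, bin_density(vals, breaks), length(vals), "angle",
               n_skipped = skipped)
}

#' Dihedral-angle distribution between consecutive bead quadruples
#'
#' Signed dihedrals in `(-180, 180]` degrees, IUPAC convention (cis = 0,
#' trans = 180). Quadruples with a collinear inner triple are skipped and
#' tallied.
#'
#' @inheritParams angle_distribution
#' @export
dihedral_distribution <- function(cgtraj, bin_width = 2, breaks = NULL) {
  require_cg(cgtraj)
  topo <- cgtraj$topology
  if (topo$N < 4) stop("at least 4 beads per chain are required")
  quads <- bead_tuples(topo, 4L)
  vals <- unlist(lapply(cgtraj$frames, function(fr)
    cpp_dihedrals(fr$positions, fr$box, quads)))
  skipped <- sum(is.na(vals)); vals <- vals[!is.na(vals)]
  if (is.null(breaks)) breaks <- seq(-180, 180, by = bin_width)
  cg_histogram(breaks, bin_density(vals, breaks), length(vals), "dihedral",
               n_skipped = skipped)
}

#' Monomeric radial distribution function with bonded exclusions
#'
#' Standard `g(r)` at the system's bead density: all intermolecular pairs
#' plus the intramolecular pairs separated by more than `exclusion_bonds`
#' bonds along the chain. The short-range intramolecular structure is the job
#' of the bonded potentials, so it is excluded from the nonbonded target.
#'
#' @inheritParams bond_distribution
#' @param bin_width bin width, nm.
#' @param r_max histogram range; must not exceed half the smallest box edge.
#'   Default `min(2.0, half box)`.
#' @param exclusion_bonds intramolecular pairs up to this bond separation are
#'   excluded (default 3).
#' @export
monomeric_rdf <- function(cgtraj, bin_width = 0.01, r_max = NULL,
                          exclusion_bonds = 3L) {
  require_cg(cgtraj)
  topo <- cgtraj$topology
  half_box <- min(vapply(cgtraj$frames, function(fr) min(fr$box), numeric(1))) / 2
  if (is.null(r_max)) r_max <- min(2.0, half_box)
  if (r_max > half_box + 1e-9)
    stop(sprintf("r_max = %.3f nm exceeds half the smallest box edge (%.3f nm)",
                 r_max, half_box))
  n_bins <- max(1L, round(r_max / bin_width))
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  chain0 <- bead_chain(topo) - 1L
  mono0 <- bead_index(topo) - 1L
  nb <- n_beads(topo)

  acc <- numeric(n_bins); norm <- numeric(n_bins)
  for (fr in cgtraj$frames) {
    acc <- acc + cpp_rdf_count(fr$positions, fr$box, chain0, mono0,
                               as.integer(exclusion_bonds), r_max, n_bins)
    V <- prod(fr$box)
    rho <- nb / V
    shell <- 4 / 3 * pi * (tail(breaks, -1)^3 - head(breaks, -1)^3)
    norm <- norm + nb * rho * shell
  }
  g <- ifelse(norm > 0, acc / norm, 0)
  h <- cg_histogram(breaks, g, sum(acc) / 2, "rdf")
  attr(h, "exclusion_bonds") <- as.integer(exclusion_bonds)
  h
}

#' The four-target distribution set driving the coarse-graining
#'
#' @param bond,angle,dihedral,rdf [cg_histogram()] objects.
#' @param temperature temperature the distributions were sampled at, K.
#' @export
distribution_set <- function(bond, angle, dihedral, rdf, temperature = 500) {
  structure(list(bond = bond, angle = angle, dihedral = dihedral, rdf = rdf,
                 temperature = temperature),
            class = "distribution_set")
}

#' Measure all four target distributions from a CG trajectory
#'
#' @param cgtraj a `cg_trajectory`.
#' @param bin_widths named list of bin widths (`bond` nm, `angle` deg,
#'   `dihedral` deg, `rdf` nm).
#' @param r_max RDF range, nm.
#' @param exclusion_bonds RDF intramolecular exclusion depth.
#' @param temperature sampling temperature, K.
#' @param template a `distribution_set` whose bin grids should be reused
#'   (the IBI loop measures current distributions on the target grids).
#' @export
measure_distributions <- function(cgtraj,
                                  bin_widths = list(bond = 0.002, angle = 1,
                                                    dihedral = 2, rdf = 0.01),
                                  r_max = NULL, exclusion_bonds = 3L,
                                  temperature = 500, template = NULL) {
  br <- function(k) if (is.null(template)) NULL else hist_breaks(template[[k]])
  rmax_t <- if (is.null(template)) r_max else max(hist_breaks(template$rdf))
  bond <- bond_distribution(cgtraj, bin_widths$bond, breaks = br("bond"))
  angle <- angle_distribution(cgtraj, bin_widths$angle, breaks = br("angle"))
  dihedral <- dihedral_distribution(cgtraj, bin_widths$dihedral, breaks = br("dihedral"))
  rdf <- monomeric_rdf(cgtraj, bin_widths$rdf, r_max = rmax_t,
                       exclusion_bonds = exclusion_bonds)
  distribution_set(bond, angle, dihedral, rdf, temperature)
}

#' @export
print.distribution_set <- function(x, ...) {
  cat(sprintf("distribution_set at %g K (bond/angle/dihedral/rdf; %d bond samples)\n",
              x$temperature, attr(x$bond, "n_samples")))
  invisible(x)
}

#' Write / read a histogram as two-column text
#'
#' `#`-metadata header, then `bin center  density` rows. These files are the
#' IBI target inputs.
#'
#' @param h a [cg_histogram()].
#' @param path file path.
#' @export
write_histogram <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  br <- hist_breaks(h)
  writeLines(c(
    sprintf("# cgmelt histogram; observable=%s n_samples=%d", hist_observable(h),
            as.integer(attr(h, "n_samples"))),
    sprintf("# edges: first=%.10e width=%.10e nbin=%d", br[1], br[2] - br[1],
            length(br) - 1)), con)
  writeLines(sprintf("%.10e %.10e", h$x, h$density), con)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  obs <- regmatches(meta[1], regexec("observable=(\\w+)", meta[1]))[[1]][2]
  ns <- as.integer(regmatches(meta[1], regexec("n_samples=(\\d+)", meta[1]))[[1]][2])
  ed <- regmatches(meta[2],
                   regexec("first=([-0-9.eE+]+) width=([-0-9.eE+]+) nbin=(\\d+)",
                           meta[2]))[[1]]
  first <- as.numeric(ed[2]); width <- as.numeric(ed[3]); nbin <- as.integer(ed[4])
  breaks <- first + width * (0:nbin)
  fields <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  cg_histogram(breaks, fields[, 2], ns, obs)
}

#' @rdname write_histogram
#' @param dset a [distribution_set()].
#' @param dir directory; one `<observable>.dist` file per histogram.
#' @export
write_distribution_set <- function(dset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in c("bond", "angle", "dihedral", "rdf"))
    write_histogram(dset[[k]], file.path(dir, paste0(k, ".dist")))
  writeLines(sprintf("temperature %g", dset$temperature),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_histogram
#' @export
read_distribution_set <- function(dir) {
  h <- lapply(setNames(nm = c("bond", "angle", "dihedral", "rdf")), function(k)
    read_histogram(file.path(dir, paste0(k, ".dist"))))
  temperature <- 500
  mp <- file.path(dir, "meta.txt")
  if (file.exists(mp))
    temperature <- as.numeric(sub("^temperature +", "", readLines(mp)[1]))
  distribution_set(h$bond, h$angle, h$dihedral, h$rdf, temperature)
}
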