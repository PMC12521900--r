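# straight-chain fixture helper: n beads along x with spacing b
straight_cg <- function(N, n_chains = 1, b = 0.66, box = 50) {
  topo <- cg_topology(N, n_chains)
  pos <- do.call(rbind, lapply(seq_len(n_chains), function(c)
    cbind(b * (seq_len(N) - 1) + c, c, c)))
  cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, rep(box, 3)))), topo)
}

test_that("a delta bond distribution occupies the single bin containing 0.66", {
  cg <- straight_cg(5)
  # bin edges offset so the exact bond length falls mid-bin
  h <- bond_distribution(cg, breaks = seq(0.601, 0.721, by = 0.002))
  occupied <- h$x[h$density > 0]
  expect_length(occupied, 1)
  expect_lt(abs(occupied - 0.66), 0.002)
  br <- attr(h, "breaks")
  expect_equal(sum(h$density * diff(br)), 1, tolerance = 1e-9)
})

test_that("Gaussian bond lengths are recovered within 3 standard errors", {
  n_chain <- 2000
  topo <- cg_topology(2, n_chain)
  b <- withr::with_seed(5, rnorm(n_chain, 0.66, 0.03))
  pos <- do.call(rbind, lapply(seq_len(n_chain), function(i)
    rbind(c(i %% 50, i %/% 50, 0), c(i %% 50 + b[i], i %/% 50, 0))))
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(1000, 1000, 1000)))), topo)
  h <- bond_distribution(cg, bin_width = 0.002)
  br <- attr(h, "breaks")
  w <- diff(br)
  mu <- sum(h$x * h$density * w)
  s2 <- sum((h$x - mu)^2 * h$density * w)
  se_mu <- 0.03 / sqrt(n_chain)
  expect_lt(abs(mu - 0.66), 3 * se_mu + 0.002)      # plus one bin of quantization
  expect_lt(abs(sqrt(s2) - 0.03), 3 * 0.03 / sqrt(2 * n_chain) + 0.002)
})

test_that("bond distribution on an empty trajectory errors", {
  topo <- cg_topology(2, 1)
  tr <- structure(list(frames = list(), times = numeric(0), topology = topo),
                  class = c("cg_trajectory", "trajectory"))
  expect_error(bond_distribution(tr), "empty")
})

test_that("collinear and right-angle triples give 180 and 90 degrees", {
  cg <- straight_cg(3)
  h <- angle_distribution(cg, bin_width = 1)
  expect_lt(abs(h$x[which.max(h$density)] - 179.5), 1)

  topo <- cg_topology(3, 1)
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  cg90 <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(50, 50, 50)))), topo)
  h90 <- angle_distribution(cg90, bin_width = 1)
  expect_lt(abs(h90$x[which.max(h90$density)] - 90), 1)
})

test_that("angle histogram equals the brute-force angle enumeration", {
  topo <- cg_topology(6, 4)
  pos <- random_chain_config(4, 6, seed = 31)
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(100, 100, 100)))), topo)
  h <- angle_distribution(cg, bin_width = 5)
  # oracle: plain acos over every consecutive triple
  angles <- c()
  for (c in 0:3) for (i in 1:4) {
    a <- pos[c * 6 + i, ] - pos[c * 6 + i + 1, ]
    b <- pos[c * 6 + i + 2, ] - pos[c * 6 + i + 1, ]
    angles <- c(angles, acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi)
  }
  expected <- hist(angles, breaks = attr(h, "breaks"), plot = FALSE)$density
  expect_equal(h$density, expected, tolerance = 1e-9)
})

test_that("planar cis and trans quadruples give 0 and 180 degrees", {
  topo <- cg_topology(4, 1)
  cis <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  trans <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  box <- c(50, 50, 50)
  v_cis <- cgmelt:::cpp_dihedrals(cis, box, cgmelt:::bead_tuples(topo, 4L))
  v_trans <- cgmelt:::cpp_dihedrals(trans, box, cgmelt:::bead_tuples(topo, 4L))
  expect_equal(abs(v_cis), 0, tolerance = 1e-10)
  expect_equal(abs(v_trans), 180, tolerance = 1e-10)
})

test_that("dihedrals match an independent geometric oracle to 1e-9 degrees", {
  topo <- cg_topology(4, 20)
  pos <- random_chain_config(20, 4, seed = 41)
  box <- c(100, 100, 100)
  got <- cgmelt:::cpp_dihedrals(pos, box, cgmelt:::bead_tuples(topo, 4L))
  # oracle: Gram-Schmidt construction of the two half-plane normals
  oracle <- sapply(0:19, function(c) {
    p <- pos[c * 4 + 1:4, ]
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
    atan2(sum(pracma::cross(n1, n2) * b2 / sqrt(sum(b2^2))),
          sum(n1 * n2)) * 180 / pi
  })
  expect_equal(as.numeric(got), oracle, tolerance = 1e-9)
})

test_that("a degenerate angle triple is skipped and tallied", {
  topo <- cg_topology(3, 1)
  pos <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 1, 1))   # coincident beads
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(10, 10, 10)))), topo)
  h <- angle_distribution(cg)
  expect_equal(attr(h, "n_skipped"), 1L)
  expect_equal(attr(h, "n_samples"), 0L)
})

test_that("the 3-bond exclusion leaves only the (1,5) pair of a 5-bead chain", {
  topo <- cg_topology(5, 1)
  b <- 0.3
  pos <- cbind(b * (0:4), 0.5, 0.5)
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(4, 4, 4)))), topo)
  h <- monomeric_rdf(cg, bin_width = 0.01, r_max = 1.9, exclusion_bonds = 3)
  # only the 1-5 pair at distance 4b = 1.2 nm contributes
  occupied <- h$x[h$density > 0]
  expect_length(occupied, 1)
  expect_lt(abs(occupied - 1.2), 0.01)
  # exclusion count per chain of N beads: (N-1) + (N-2) + (N-3)
  N <- 5
  n_pairs_total <- N * (N - 1) / 2
  expect_equal(n_pairs_total - ((N - 1) + (N - 2) + (N - 3)), 1)
})

test_that("an ideal-gas configuration has g(r) = 1 within 3 standard errors", {
  n <- 1500
  topo <- cg_topology(1, n)
  L <- 8
  pos <- withr::with_seed(7, matrix(runif(3 * n, 0, L), ncol = 3))
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, rep(L, 3)))), topo)
  h <- monomeric_rdf(cg, bin_width = 0.05, r_max = 2.0)
  # Poisson counting error per bin
  br <- attr(h, "breaks")
  shell <- 4 / 3 * pi * (tail(br, -1)^3 - head(br, -1)^3)
  expected_counts <- n * (n / L^3) * shell
  se <- 1 / sqrt(expected_counts)
  z <- abs(h$density - 1) / se
  expect_lt(mean(z > 3), 0.06)        # at most an outlier or two in 40 bins
  expect_lt(abs(mean(h$density[h$x > 1]) - 1), 0.02)
})

test_that("pair histogram equals a brute-force minimum-image double loop", {
  topo <- cg_topology(4, 2)
  L <- 2.4
  pos <- withr::with_seed(3, matrix(runif(24, 0, L), ncol = 3))
  cg <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, rep(L, 3)))), topo)
  h <- monomeric_rdf(cg, bin_width = 0.05, r_max = 1.1, exclusion_bonds = 3)
  # oracle: explicit double loop
  br <- attr(h, "breaks")
  counts <- numeric(length(br) - 1)
  chain <- rep(1:2, each = 4); mono <- rep(1:4, 2)
  for (i in 1:7) for (j in (i + 1):8) {
    if (chain[i] == chain[j] && abs(mono[i] - mono[j]) <= 3) next
    d <- pos[i, ] - pos[j, ]
    d <- d - round(d / L) * L
    r <- sqrt(sum(d^2))
    if (r < 1.1) {
      b <- findInterval(r, br, rightmost.closed = TRUE)
      counts[b] <- counts[b] + 2
    }
  }
  V <- L^3; rho <- 8 / V
  shell <- 4 / 3 * pi * (tail(br, -1)^3 - head(br, -1)^3)
  expect_equal(h$density, counts / (8 * rho * shell), tolerance = 1e-9)
})

test_that("r_max beyond half the box is rejected with the constraint named", {
  cg <- straight_cg(5, box = 3)
  expect_error(monomeric_rdf(cg, r_max = 2.0), "half the smallest box edge")
})

test_that("distributions are invariant under rigid translation and chain relabeling", {
  topo <- cg_topology(5, 6)
  pos <- random_chain_config(6, 5, seed = 77, box = 3)
  # jitter so no sample sits exactly on a bin edge
  pos <- pos + withr::with_seed(78, matrix(rnorm(length(pos), sd = 0.01),
                                           nrow(pos)))
  box <- c(6, 6, 6)
  mk <- function(p) cgmelt:::as_cg_trajectory(trajectory(list(frame(p, box))), topo)
  h1 <- measure_distributions(mk(pos), r_max = 1.5)
  shifted <- sweep(pos, 2, c(1.3, -0.7, 2.9), "+")
  h2 <- measure_distributions(mk(shifted), template = h1)
  perm <- as.vector(sapply(c(4, 2, 6, 1, 5, 3), function(c) (c - 1) * 5 + 1:5))
  h3 <- measure_distributions(mk(pos[perm, ]), template = h1)
  for (k in c("bond", "angle", "dihedral", "rdf")) {
    expect_equal(h2[[k]]$density, h1[[k]]$density, tolerance = 1e-9)
    expect_equal(h3[[k]]$density, h1[[k]]$density, tolerance = 1e-9)
  }
})

test_that("histogram files round-trip through the two-column text format", {
  cg <- straight_cg(5)
  h <- bond_distribution(cg, bin_width = 0.002)
  path <- withr::local_tempfile(fileext = ".dist")
  write_histogram(h, path)
  back <- read_histogram(path)
  expect_equal(back$x, h$x, tolerance = 1e-9)
  expect_equal(back$density, h$density, tolerance = 1e-9)
  expect_equal(attr(back, "observable"), "bond")
})
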