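test_that("a straight rod has R_n^2/n = n (unit spacing) and asphericity 1", {
  topo <- cg_topology(20, 1)
  pos <- cbind(0:19, 0, 0)
  tr <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(100, 100, 100)))), topo)
  prof <- internal_distances(tr)
  expect_equal(prof$ratio, prof$n, tolerance = 1e-12)
  expect_equal(gyration_analysis(rbind(c(0, 0, 0), c(0, 0, 2)))$asphericity, 1,
               tolerance = 1e-12)
})

test_that("freely jointed chains have flat R_n^2/n = b^2 and C_n = 1", {
  b <- 0.66
  tr <- generate_ideal_chains(N = 30, n_chains = 3000, bond_length = b,
                              kind = "fjc", seed = 23)
  prof <- internal_distances(tr)
  # each separation averaged over >= 3000 samples; 3 standard errors
  se <- b^2 * sqrt(2 / (3000 * (30 - prof$n)))
  expect_true(all(abs(prof$ratio - b^2) < 3.5 * se))
  cn <- characteristic_ratio(tr, level = "monomer")
  expect_equal(cn$C_n[1], 1, tolerance = 1e-12)
  expect_lt(abs(attr(cn, "C_inf") - 1), 0.05)
})

test_that("R_N^2 at full separation equals the independently computed Re^2", {
  tr <- generate_ideal_chains(N = 12, n_chains = 500, kind = "fjc", seed = 3)
  prof <- internal_distances(tr)
  sh <- chain_shapes(tr)
  expect_equal(prof$msd[11], mean(sh$Re^2), tolerance = 1e-10)
})

test_that("freely rotating chains reach the closed-form characteristic ratio", {
  theta <- 120
  tr <- generate_ideal_chains(N = 120, n_chains = 1500, bond_length = 0.5,
                              kind = "frc", bond_angle = theta, seed = 31)
  cn <- characteristic_ratio(tr, level = "monomer")
  # oracle: direct double-sum over the bond-correlation powers
  alpha <- -cos(theta * pi / 180)
  n_top <- cn$n[cn$n > max(cn$n) * 0.9]
  cinf_ref <- mean(vapply(n_top, function(n) {
    idx <- seq_len(n)
    sum(alpha^abs(outer(idx, idx, "-"))) / n
  }, numeric(1)))
  expect_lt(abs(attr(cn, "C_inf") - cinf_ref) / cinf_ref, 0.05)
})

test_that("the gyration tensor double sum equals the centered form exactly", {
  pos <- withr::with_seed(11, matrix(rnorm(90), 30, 3))
  g <- gyration_analysis(pos)
  # brute-force O(N^2) double sum
  T_brute <- matrix(0, 3, 3)
  for (i in 1:30) for (j in 1:30)
    T_brute <- T_brute + outer(pos[i, ] - pos[j, ], pos[i, ] - pos[j, ])
  T_brute <- T_brute / (2 * 30^2)
  expect_equal(g$tensor, T_brute, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$Rg2, sum(g$eigenvalues), tolerance = 1e-12)
  ev_ref <- sort(eigen(T_brute, symmetric = TRUE)$values)
  a_ref <- ((ev_ref[2] - ev_ref[1])^2 + (ev_ref[3] - ev_ref[1])^2 +
              (ev_ref[3] - ev_ref[2])^2) / (2 * sum(ev_ref)^2)
  expect_equal(g$asphericity, a_ref, tolerance = 1e-12)
})

test_that("a regular tetrahedron has asphericity 0 and coincident points error", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(gyration_analysis(tet)$asphericity, 0, tolerance = 1e-12)
  expect_error(gyration_analysis(matrix(1, 5, 3)), "coincident")
})

test_that("asphericity is bounded and invariant under rigid motion and dilation", {
  withr::with_seed(4, for (i in 1:10) {
    pos <- matrix(rnorm(45), 15, 3)
    a0 <- gyration_analysis(pos)$asphericity
    expect_gte(a0, 0); expect_lte(a0, 1)
    th <- runif(1, 0, pi)
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    moved <- sweep(pos %*% R, 2, rnorm(3), "+") * runif(1, 0.5, 3)
    expect_equal(gyration_analysis(moved)$asphericity, a0, tolerance = 1e-10)
  })
})

test_that("single beads and the q->0 limit give W/Np = 1", {
  topo <- cg_topology(1, 4)
  pos <- matrix(runif(12, 0, 3), 4, 3)
  tr <- cgmelt:::as_cg_trajectory(trajectory(list(frame(pos, c(50, 50, 50)))), topo)
  ff <- form_factor(tr, q = c(0.5, 1, 5))
  expect_equal(ff$W, rep(1, 3), tolerance = 1e-12)

  tr2 <- generate_ideal_chains(N = 20, n_chains = 50, kind = "fjc", seed = 2)
  ff2 <- form_factor(tr2, q = c(1e-4, 1e-3))
  expect_equal(ff2$W, rep(1, 2), tolerance = 1e-4)
  expect_error(form_factor(tr2, q = c(0, 1)), "positive")
})

test_that("Gaussian chains match the Debye function within 0.02", {
  tr <- generate_ideal_chains(N = 125, n_chains = 2000, bond_length = 0.66,
                              kind = "fjc", seed = 8)
  sh <- chain_shapes(tr)
  Rg2 <- mean(sh$Rg2)
  q <- exp(seq(log(0.2), log(3), length.out = 30))
  ff <- form_factor(tr, q = q)
  x <- q^2 * Rg2
  debye <- 2 * (exp(-x) - 1 + x) / x^2
  expect_lt(max(abs(ff$W - debye)), 0.02)
})

test_that("scaling_fit recovers exact power laws and ideal-chain scaling", {
  N <- c(10, 30, 50, 100, 125)
  expect_equal(scaling_fit(2 * N^0.5, N), 0.5, tolerance = 1e-12)
  expect_equal(scaling_fit(0.3 * N, N), 1, tolerance = 1e-12)
  expect_error(scaling_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # simulated ideal chains across the catalogue lengths
  rg <- vapply(N, function(n) {
    tr <- generate_ideal_chains(N = n, n_chains = 600, kind = "fjc",
                                seed = 100 + n)
    sqrt(mean(chain_shapes(tr)$Rg2))
  }, numeric(1))
  nu <- scaling_fit(rg, N)
  expect_lt(abs(nu - 0.5), 0.02)
})

test_that("packing length follows its definition and proportionalities", {
  p0 <- packing_length(14270, 95, 928)
  expect_equal(packing_length(14270, 95, 2 * 928), p0 / 2, tolerance = 1e-12)
  expect_equal(packing_length(2 * 14270, 95, 928), 2 * p0, tolerance = 1e-12)
  expect_error(packing_length(100, 10, 0), "positive")
  # consistency chain: C_inf = 5, b = 0.148 nm, 7 N backbone bonds, N = 125
  Re2 <- 5 * (7 * 125) * 0.148^2
  expect_lt(abs(packing_length(14270, Re2, 928) - 0.27), 0.01)
})

test_that("packing length is chain-length independent for ideal melts", {
  b <- 0.66; rho <- 930
  p_vals <- vapply(c(20, 50, 100), function(N) {
    tr <- generate_ideal_chains(N = N, n_chains = 1200, bond_length = b,
                                kind = "fjc", density = rho, seed = 300 + N)
    Re2 <- mean(chain_shapes(tr)$Re^2)
    packing_length(N * 114.144, Re2, rho)
  }, numeric(1))
  expect_lt(max(abs(p_vals - mean(p_vals))) / mean(p_vals), 0.1)
})

test_that("entanglement estimates reproduce the packing-length relation", {
  # monomer molar mass at the printed precision of the other inputs
  est <- entanglement_estimates(p = 0.27, rho = 928, n_t = 21,
                                monomer_mass = 114.14)
  expect_equal(est$M_e, 4851, tolerance = 1e-3)
  expect_equal(est$N_e, 43)           # 4851 / 114.14 = 42.50, rounds up
  expect_equal(est$M_c, 2 * est$M_e)
  expect_equal(est$onset_N, 2 * est$N_e)
  expect_error(entanglement_estimates(-1, 928), "positive")
})

test_that("ideal ensembles approach Re^2/Rg^2 = 6 as chains grow", {
  r_short <- local({
    tr <- generate_ideal_chains(N = 5, n_chains = 3000, kind = "fjc", seed = 51)
    sh <- chain_shapes(tr); mean(sh$Re^2) / mean(sh$Rg2)
  })
  r_long <- local({
    tr <- generate_ideal_chains(N = 150, n_chains = 3000, kind = "fjc", seed = 52)
    sh <- chain_shapes(tr); mean(sh$Re^2) / mean(sh$Rg2)
  })
  expect_gt(abs(r_short - 6), abs(r_long - 6))
  expect_lt(abs(r_long - 6), 0.15)
})
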