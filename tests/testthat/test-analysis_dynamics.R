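# synthetic trajectory builders for dynamic observables
traj_from_positions <- function(pos_list, topo, box = 100, dt = 1) {
  frames <- lapply(seq_along(pos_list), function(i)
    frame(pos_list[[i]], rep(box, 3), (i - 1) * dt))
  cgmelt:::as_cg_trajectory(trajectory(frames), topo)
}

test_that("the end-to-end ACF is 1 at zero lag and for frozen trajectories", {
  topo <- cg_topology(5, 8)
  pos <- random_chain_config(8, 5, seed = 2)
  tr <- traj_from_positions(replicate(20, pos, simplify = FALSE), topo)
  acf <- end_to_end_acf(tr)
  expect_equal(acf$C[acf$time == 0], 1)
  expect_true(all(abs(acf$C - 1) < 1e-12))
})

test_that("isotropically redrawn orientations decorrelate to zero", {
  topo <- cg_topology(2, 60)
  pos_list <- withr::with_seed(9, lapply(1:300, function(i) {
    u <- matrix(rnorm(180), 60, 3)
    u <- u / sqrt(rowSums(u^2))
    starts <- matrix(runif(180, 0, 50), 60, 3)
    out <- matrix(NA_real_, 120, 3)
    out[seq(1, 119, 2), ] <- starts
    out[seq(2, 120, 2), ] <- starts + u
    out
  }))
  tr <- traj_from_positions(pos_list, topo)
  acf <- end_to_end_acf(tr, origin_stride = 5)
  late <- acf[acf$time > 0, ]
  # 60 chains x ~60 origins, heavy reuse: allow 3 se of the pooled estimate
  se <- 1 / sqrt(60 * late$n_origins / 3)
  expect_true(all(abs(late$C) < 3.5 * se + 0.02))
})

test_that("KWW fitting recovers exact and noisy parameters", {
  # noiseless pure exponential
  t <- seq(0.5, 60, by = 0.5)
  curve <- tibble::tibble(time = t, C = exp(-t / 10))
  f <- fit_kww(curve, noise_floor = 1e-4)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_equal(f$tau, 10, tolerance = 1e-5)
  expect_equal(f$beta, 1, tolerance = 1e-5)

  # seeded noisy stretched exponential
  g <- generate_kww_curve(A = 0.98, tau = 10, beta = 0.6, sigma = 0.01, seed = 4)
  f2 <- fit_kww(g)
  expect_lt(abs(f2$A - 0.98) / 0.98, 0.05)
  expect_lt(abs(f2$tau - 10) / 10, 0.05)
  expect_lt(abs(f2$beta - 0.6) / 0.6, 0.05)
})

test_that("KWW recovery bias stays below 5% over a seeded grid of curves", {
  pars <- expand.grid(tau = c(5, 20), beta = c(0.5, 0.7, 0.9, 1.1),
                      A = c(0.9, 0.98))
  est <- t(vapply(seq_len(nrow(pars)), function(i) {
    g <- generate_kww_curve(A = pars$A[i], tau = pars$tau[i],
                            beta = pars$beta[i], sigma = 0.01, seed = 100 + i)
    f <- fit_kww(g)
    c(f$A, f$tau, f$beta)
  }, numeric(3)))
  # bias (mean signed relative error) across the grid stays below 5%;
  # individual stretched-exponential fits carry correlated A-tau-beta errors
  expect_lt(abs(mean((est[, 1] - pars$A) / pars$A)), 0.05)
  expect_lt(abs(mean((est[, 2] - pars$tau) / pars$tau)), 0.05)
  expect_lt(abs(mean((est[, 3] - pars$beta) / pars$beta)), 0.05)
  expect_lt(mean(abs(est[, 2] - pars$tau) / pars$tau), 0.1)
})

test_that("tidy and glance expose the KWW fit in broom form", {
  f <- fit_kww(generate_kww_curve(seed = 3))
  td <- generics::tidy(f)
  expect_equal(td$term, c("A", "tau", "beta"))
  expect_true(all(is.finite(td$estimate)))
  gl <- generics::glance(f)
  expect_true(all(c("tau_end", "sigma", "n") %in% names(gl)))
})

test_that("the terminal time has its closed forms and matches quadrature", {
  expect_equal(terminal_time(7.3, 1), 7.3)
  expect_equal(terminal_time(4, 0.5), 8)     # (tau/0.5) Gamma(2) = 2 tau
  # quadrature oracle for the fitted PCL10-like parameters
  tau <- 1.42; beta <- 0.73
  quad <- integrate(function(t) exp(-(t / tau)^beta), 0, Inf)$value
  expect_lt(abs(terminal_time(tau, beta) - quad) / quad, 1e-3)
  expect_error(terminal_time(-1, 0.5), "positive")
})

test_that("tau_end is consistent with the integral of any fitted curve", {
  withr::with_seed(6, for (i in 1:5) {
    g <- generate_kww_curve(A = runif(1, 0.85, 1), tau = runif(1, 3, 30),
                            beta = runif(1, 0.4, 1.2), sigma = 0.005,
                            seed = 200 + i)
    f <- fit_kww(g)
    quad <- integrate(function(t) exp(-(t / f$tau)^f$beta), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_lt(abs(f$tau_end - quad) / quad, 1e-3)
  })
})

test_that("the COM MSD is zero for static systems and (vt)^2 under drift", {
  topo <- cg_topology(4, 3)
  pos <- random_chain_config(3, 4, seed = 5)
  static <- traj_from_positions(replicate(15, pos, simplify = FALSE), topo)
  ms <- com_msd(static)
  expect_true(all(ms$g1 < 1e-20))

  v <- c(0.03, -0.01, 0.02)
  drift <- traj_from_positions(lapply(0:14, function(i)
    sweep(pos, 2, i * v, "+")), topo)
  md <- com_msd(drift)
  expect_equal(md$g1, sum(v^2) * md$time^2, tolerance = 1e-10)
})

test_that("Brownian centers of mass give an Einstein slope of 6D", {
  D <- 0.05  # nm^2/ps
  dt <- 1
  nch <- 150; nf <- 400
  topo <- cg_topology(1, nch)
  steps <- withr::with_seed(12, array(rnorm(nf * nch * 3, sd = sqrt(2 * D * dt)),
                                      c(nf, nch, 3)))
  pos_list <- lapply(seq_len(nf), function(i) {
    if (i == 1) matrix(50, nch, 3)
    else matrix(50 + apply(steps[2:i, , , drop = FALSE], c(2, 3), sum), nch, 3)
  })
  tr <- traj_from_positions(pos_list, topo, box = 1e4, dt = dt)
  ms <- com_msd(tr, origin_stride = 4)
  fit_pts <- ms$time > 0 & ms$time <= 50
  slope <- unname(coef(lm(ms$g1[fit_pts] ~ 0 + ms$time[fit_pts])))
  expect_lt(abs(slope - 6 * D) / (6 * D), 0.05)
})

test_that("wrapped center-of-mass input is rejected", {
  topo <- cg_topology(1, 1)
  frames <- list(frame(matrix(c(0.1, 1, 1), 1), c(2, 2, 2), 0),
                 frame(matrix(c(1.9, 1, 1), 1), c(2, 2, 2), 1))
  tr <- cgmelt:::as_cg_trajectory(trajectory(frames), topo)
  expect_error(com_msd(tr), "wrapped input")
})

test_that("time-scaling factors reproduce the tabulated shift factors", {
  # characteristic-time route on the published characteristic times
  ts10 <- time_scaling_factors(1.42, 0.12)
  expect_equal(round(ts10$t_cg), 12)
  ts50 <- time_scaling_factors(42, 2.7)
  expect_equal(round(ts50$t_cg), 16)
  # identical dynamics at both resolutions gives factors of exactly 1
  msd <- tibble::tibble(time = 1:100, g1 = 0.01 * (1:100))
  class(msd) <- c("msd_curve", class(msd))
  same <- time_scaling_factors(5, 5, msd, msd, Rg2_A = 0.5)
  expect_equal(same$t_cg, 1)
  expect_equal(same$t_cg_msd, 1)
  expect_equal(same$t1_A, same$t1_CG)
})

test_that("the MSD route interpolates crossings log-log and reports NA otherwise", {
  msd_A <- tibble::tibble(time = c(1, 10, 100), g1 = c(0.01, 1, 100))
  msd_B <- tibble::tibble(time = c(1, 10, 100), g1 = c(0.04, 4, 400))
  class(msd_A) <- c("msd_curve", class(msd_A))
  class(msd_B) <- c("msd_curve", class(msd_B))
  ts <- time_scaling_factors(1, 1, msd_A, msd_B, Rg2_A = 10)
  # g1 = 0.01 t^2 crosses 10 at t = sqrt(1000); g1 = 0.04 t^2 at t = sqrt(250)
  expect_equal(ts$t1_A, sqrt(1000), tolerance = 1e-6)
  expect_equal(ts$t1_CG, sqrt(250), tolerance = 1e-6)
  expect_equal(ts$t_cg_msd, 2, tolerance = 1e-6)
  # no crossing: NA, not an extrapolation
  low <- tibble::tibble(time = c(1, 10), g1 = c(0.001, 0.002))
  class(low) <- c("msd_curve", class(low))
  ts2 <- time_scaling_factors(1, 1, low, msd_B, Rg2_A = 10)
  expect_true(is.na(ts2$t_cg_msd))
})
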