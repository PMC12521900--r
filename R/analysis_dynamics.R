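# end-to-end vectors per frame: n_frames x n_chains x 3 array
end_to_end_vectors <- function(traj, topology, level) {
  npc <- particles_per_chain(topology, level)
  nf <- n_frames(traj); nc <- topology$n_chains
  E <- array(NA_real_, c(nf, nc, 3))
  first <- (seq_len(nc) - 1) * npc + 1
  last <- seq_len(nc) * npc
  for (fi in seq_len(nf)) {
    p <- chain_major_positions(traj$frames[[fi]], topology, level)
    E[fi, , ] <- p[last, , drop = FALSE] - p[first, , drop = FALSE]
  }
  E
}

default_lags <- function(nf, max_lag_frames) {
  lags <- unique(round(exp(seq(0, log(max_lag_frames), length.out = 60))))
  c(0, lags[lags >= 1 & lags <= max_lag_frames])
}

#' Orientational autocorrelation of the end-to-end vector
#'
#' `C(t) = < cos angle(Re(t0 + t), Re(t0)) >`, the per-sample-normalized
#' form, averaged over chains and multiple time origins. Lags are
#' log-spaced to span decades economically. Samples with a zero-length
#' end-to-end vector are skipped and tallied.
#'
#' @param traj a [trajectory()] or `cg_trajectory` with uniform sampling.
#' @param topology a `system_topology`; taken from the trajectory if present.
#' @param max_lag maximum lag, ps (default: 3/4 of the trajectory span).
#' @param origin_stride frames between time origins.
#' @param level particle level for the chain ends (defaults as in
#'   [internal_distances()]).
#' @return an `acf_curve` tibble with `time` (ps), `C` and `n_origins`.
#' @export
end_to_end_acf <- function(traj, topology = NULL, max_lag = NULL,
                           origin_stride = 1L, level = NULL) {
  rl <- resolve_level(traj, topology, level)
  nf <- n_frames(traj)
  if (nf < 2) stop("at least 2 frames are required")
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
    stop("uniform frame sampling is required")
  dt <- dts[1]
  max_lag_frames <- if (is.null(max_lag)) max(1L, floor(0.75 * (nf - 1)))
    else min(nf - 1L, floor(max_lag / dt))
  E <- end_to_end_vectors(traj, rl$topology, rl$level)
  norms <- sqrt(E[, , 1]^2 + E[, , 2]^2 + E[, , 3]^2)
  skipped <- 0L
  lags <- default_lags(nf, max_lag_frames)
  res <- vapply(lags, function(lag) {
    origins <- seq(1L, nf - lag, by = origin_stride)
    dots <- E[origins, , 1] * E[origins + lag, , 1] +
      E[origins, , 2] * E[origins + lag, , 2] +
      E[origins, , 3] * E[origins + lag, , 3]
    den <- norms[origins, ] * norms[origins + lag, ]
    ok <- den > 0
    skipped <<- skipped + sum(!ok)
    c(mean(dots[ok] / den[ok]), length(origins))
  }, numeric(2))
  out <- tibble(time = lags * dt, C = res[1, ], n_origins = as.integer(res[2, ]))
  attr(out, "n_skipped") <- skipped
  class(out) <- c("acf_curve", class(out))
  out
}

#' Stretched-exponential (KWW) fit of a relaxation curve
#'
#' Fits `f(t) = A exp(-(t/tau)^beta)` by bounded nonlinear least squares
#' (Levenberg-Marquardt), with `A` in (0, 1], `beta` in (0, 1.5] and initial
#' guesses `tau` from the 1/e crossing, `beta = 0.7`, `A = 1`. The default
#' fit window keeps lags with `C(t)` above a noise floor of 0.05 and at
#' least 10 contributing origins. The terminal relaxation time
#' `tau_end = (tau/beta) Gamma(1/beta)` is attached.
#'
#' @param acf an `acf_curve` (or any tibble with `time` and `C`).
#' @param window logical vector or function selecting the fitted lags;
#'   `NULL` for the default noise-floor window.
#' @param noise_floor smallest `C` included in the default window.
#' @return a `kww_fit` object with elements `A`, `tau`, `beta`, `tau_end`,
#'   `cov` (asymptotic covariance), `se`, `fitted`, `data`.
#' @export
fit_kww <- function(acf, window = NULL, noise_floor = 0.05) {
  d <- acf[acf$time > 0, ]
  keep <- if (is.null(window)) {
    k <- d$C > noise_floor
    if ("n_origins" %in% names(d)) k <- k & d$n_origins >= 10
    k
  } else if (is.function(window)) window(d) else window
  d <- d[keep, ]
  if (nrow(d) < 4) stop("too few points above the noise floor to fit")
  tau0 <- d$time[which.min(abs(d$C - exp(-1)))]   # 1/e crossing
  if (!length(tau0) || !is.finite(tau0) || tau0 <= 0)
    tau0 <- stats::median(d$time)
  A0 <- min(0.999, max(max(d$C), 0.5))   # ~1, but strictly inside the bounds
  fit <- tryCatch(
    minpack.lm::nlsLM(C ~ A * exp(-(time / tau)^beta), data = d,
                      start = list(A = A0, tau = tau0, beta = 0.7),
                      lower = c(1e-6, 1e-12, 1e-3), upper = c(1, Inf, 1.5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("KWW fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(A = unname(cf["A"]), tau = unname(cf["tau"]),
                 beta = unname(cf["beta"]),
                 tau_end = terminal_time(unname(cf["tau"]), unname(cf["beta"])),
                 cov = cv, se = sqrt(pmax(diag(cv), 0)),
                 fitted = stats::fitted(fit), data = d),
            class = "kww_fit")
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("kww_fit: A = %.4f, tau = %.4g, beta = %.4f, tau_end = %.4g\n",
              x$A, x$tau, x$beta, x$tau_end))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy kww_fit
#' @export
tidy.kww_fit <- function(x, ...) {
  tibble(term = c("A", "tau", "beta"),
         estimate = c(x$A, x$tau, x$beta),
         std.error = x$se)
}

#' @method glance kww_fit
#' @export
glance.kww_fit <- function(x, ...) {
  tibble(A = x$A, tau = x$tau, beta = x$beta, tau_end = x$tau_end,
         n = nrow(x$data),
         sigma = sqrt(mean((x$data$C - x$fitted)^2)))
}

#' Terminal relaxation time of a stretched exponential
#'
#' `tau_end = (tau/beta) Gamma(1/beta)`, the time integral of
#' `exp(-(t/tau)^beta)`; comparable to rheological terminal times.
#'
#' @param tau characteristic time.
#' @param beta stretch exponent.
#' @export
terminal_time <- function(tau, beta) {
  if (any(tau <= 0) || any(beta <= 0)) stop("tau and beta must be positive")
  (tau / beta) * gamma(1 / beta)
}

#' Center-of-mass mean squared displacement
#'
#' `g1(t) = (1/Nc) sum_i < |R_COM,i(t0 + t) - R_COM,i(t0)|^2 >` over chains
#' and multiple origins. Requires unwrapped coordinates: a center-of-mass
#' jump larger than half the box between consecutive frames is treated as
#' wrapped input and rejected.
#'
#' @inheritParams end_to_end_acf
#' @return an `msd_curve` tibble with `time` (ps), `g1` (nm^2), `n_origins`,
#'   plus an `exponent` attribute: the log-log slope over the middle of the
#'   curve (sub-diffusive exponent diagnostic).
#' @export
com_msd <- function(traj, topology = NULL, max_lag = NULL, origin_stride = 1L) {
  rl <- resolve_level(traj, topology, NULL)
  topo <- rl$topology
  nf <- n_frames(traj)
  if (nf < 2) stop("at least 2 frames are required")
  dt <- diff(traj$times)[1]
  masses <- if (rl$level == "monomer" && topo$level == "cg")
    bead_masses(topo) else topo$atoms$mass
  chain <- if (rl$level == "monomer" && topo$level == "cg")
    bead_chain(topo) else topo$atoms$chain
  mc <- as.vector(tapply(masses, chain, sum))
  com <- array(NA_real_, c(nf, topo$n_chains, 3))
  for (fi in seq_len(nf)) {
    p <- traj$frames[[fi]]$positions
    for (k in 1:3)
      com[fi, , k] <- as.vector(tapply(masses * p[, k], chain, sum)) / mc
  }
  # wrapped-input detection
  if (nf > 1) {
    half <- min(vapply(traj$frames, function(f) min(f$box), numeric(1))) / 2
    jump2 <- diff(matrix(com[, , 1], nf))^2 + diff(matrix(com[, , 2], nf))^2 +
      diff(matrix(com[, , 3], nf))^2
    if (max(sqrt(jump2)) > half)
      stop("wrapped input detected: center-of-mass jump exceeds half the box between frames")
  }
  max_lag_frames <- if (is.null(max_lag)) max(1L, floor(0.75 * (nf - 1)))
    else min(nf - 1L, floor(max_lag / dt))
  lags <- default_lags(nf, max_lag_frames)
  res <- vapply(lags, function(lag) {
    origins <- seq(1L, nf - lag, by = origin_stride)
    d2 <- (com[origins + lag, , 1] - com[origins, , 1])^2 +
      (com[origins + lag, , 2] - com[origins, , 2])^2 +
      (com[origins + lag, , 3] - com[origins, , 3])^2
    c(mean(d2), length(origins))
  }, numeric(2))
  out <- tibble(time = lags * dt, g1 = res[1, ], n_origins = as.integer(res[2, ]))
  pos <- out$time > 0 & out$g1 > 0
  expo <- NA_real_
  if (sum(pos) >= 4) {
    mid <- which(pos)
    mid <- mid[seq(max(1, floor(length(mid) * 0.25)), ceiling(length(mid) * 0.75))]
    expo <- unname(coef(lm(log(out$g1[mid]) ~ log(out$time[mid])))[2])
  }
  attr(out, "exponent") <- expo
  class(out) <- c("msd_curve", class(out))
  out
}

# first crossing g1(t1) = y by log-log interpolation between bracketing samples
msd_crossing_time <- function(msd, y) {
  g <- msd$g1; t <- msd$time
  ok <- t > 0 & g > 0
  g <- g[ok]; t <- t[ok]
  above <- which(g >= y)
  if (!length(above) || above[1] == 1) return(NA_real_)
  i <- above[1]
  f <- (log(y) - log(g[i - 1])) / (log(g[i]) - log(g[i - 1]))
  exp(log(t[i - 1]) + f * (log(t[i]) - log(t[i - 1])))
}

#' Time-scaling factors between fine-grained and CG dynamics
#'
#' Two routes to the factor that maps accelerated CG time onto physical
#' time: the ratio of KWW characteristic times, `t_CG = tau_A / tau_CG`, and
#' the ratio of the times at which each center-of-mass MSD reaches the
#' squared chain size, `t_CG^MSD = t1_A / t1_CG` with `g1(t1) = Rg^2`
#' (crossings located by log-log interpolation; reported `NA` rather than
#' extrapolated when a curve never crosses).
#'
#' @param fit_A,fit_CG `kww_fit` objects, or bare characteristic times.
#' @param msd_A,msd_CG optional `msd_curve`s for the MSD route.
#' @param Rg2_A,Rg2_CG squared radii of gyration (nm^2) defining the
#'   crossing level for each resolution; `Rg2_CG` defaults to `Rg2_A`.
#' @return a `time_scaling` tibble with `t_cg`, `t_cg_msd`, `t1_A`, `t1_CG`.
#' @export
time_scaling_factors <- function(fit_A, fit_CG, msd_A = NULL, msd_CG = NULL,
                                 Rg2_A = NULL, Rg2_CG = NULL) {
  tau_of <- function(f) if (inherits(f, "kww_fit")) f$tau else as.numeric(f)
  tau_A <- tau_of(fit_A); tau_CG <- tau_of(fit_CG)
  if (tau_A <= 0 || tau_CG <= 0) stop("characteristic times must be positive")
  t1A <- t1C <- NA_real_
  if (!is.null(msd_A) && !is.null(msd_CG)) {
    if (is.null(Rg2_A)) stop("Rg2_A is required for the MSD route")
    if (is.null(Rg2_CG)) Rg2_CG <- Rg2_A
    t1A <- msd_crossing_time(msd_A, Rg2_A)
    t1C <- msd_crossing_time(msd_CG, Rg2_CG)
  }
  out <- tibble(t_cg = tau_A / tau_CG,
                t_cg_msd = if (is.finite(t1A) && is.finite(t1C)) t1A / t1C
                  else NA_real_,
                t1_A = t1A, t1_CG = t1C)
  class(out) <- c("time_scaling", class(out))
  out
}
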