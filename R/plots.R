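#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col labs
#'   scale_x_log10 scale_y_log10 theme_bw
NULL

#' @export
ggplot2::autoplot

#' Plot a target/measured distribution histogram
#'
#' @param object a [cg_histogram()].
#' @param ... ignored.
#' @method autoplot cg_histogram
#' @export
autoplot.cg_histogram <- function(object, ...) {
  xlab <- switch(hist_observable(object),
                 bond = "r (nm)", angle = "theta (deg)",
                 dihedral = "phi (deg)", rdf = "r (nm)", "x")
  ylab <- if (hist_observable(object) == "rdf") "g(r)" else "density"
  ggplot(object, aes(x = .data$x, y = .data$density)) +
    geom_line() + labs(x = xlab, y = ylab) + theme_bw()
}

#' Plot a tabulated potential
#'
#' @param object a [tabulated_potential()].
#' @param ... ignored.
#' @method autoplot tabulated_potential
#' @export
autoplot.tabulated_potential <- function(object, ...) {
  d <- tibble(x = object$grid, U = object$U)
  xlab <- if (object$kind %in% c("angle", "dihedral")) "angle (deg)" else "r (nm)"
  ggplot(d, aes(x = .data$x, y = .data$U)) + geom_line() +
    labs(x = xlab, y = "U (kJ/mol)", title = object$kind) + theme_bw()
}

#' Plot an end-to-end orientational ACF with its KWW fit if supplied
#'
#' @param object an `acf_curve`.
#' @param fit optional `kww_fit` overlay.
#' @param ... ignored.
#' @method autoplot acf_curve
#' @export
autoplot.acf_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(object[object$time > 0, ], aes(x = .data$time, y = .data$C)) +
    geom_point(size = 0.8) + scale_x_log10() +
    labs(x = "t (ps)", y = "C(t)") + theme_bw()
  if (!is.null(fit)) {
    tt <- exp(seq(log(min(object$time[object$time > 0])),
                  log(max(object$time)), length.out = 200))
    d <- tibble(time = tt, C = fit$A * exp(-(tt / fit$tau)^fit$beta))
    p <- p + geom_line(data = d, colour = "red")
  }
  p
}

#' Plot a center-of-mass MSD curve (log-log)
#'
#' @param object an `msd_curve`.
#' @param ... ignored.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(object[object$time > 0 & object$g1 > 0, ],
         aes(x = .data$time, y = .data$g1)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "t (ps)", y = "g1(t) (nm^2)") + theme_bw()
}

#' Plot a single-chain form factor (log-log) with the fitted fractal slope
#'
#' @param object a `form_factor_curve`.
#' @param ... ignored.
#' @method autoplot form_factor_curve
#' @export
autoplot.form_factor_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$q, y = .data$W)) +
    geom_line() + scale_x_log10() + scale_y_log10() +
    labs(x = "q (1/nm)", y = "W(q)/Np") + theme_bw()
  nu <- attr(object, "nu")
  if (is.finite(nu))
    p <- p + labs(title = sprintf("fitted nu = %.3f", nu))
  p
}

#' Plot internal distances R_n^2/n against separation
#'
#' @param object an `internal_distance_profile`.
#' @param ... ignored.
#' @method autoplot internal_distance_profile
#' @export
autoplot.internal_distance_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$n, y = .data$ratio)) +
    geom_line() + geom_point(size = 0.8) + scale_x_log10() +
    labs(x = "n", y = "R_n^2 / n (nm^2)") + theme_bw()
}

#' Plot the characteristic-ratio curve
#'
#' @param object a `characteristic_ratio`.
#' @param ... ignored.
#' @method autoplot characteristic_ratio
#' @export
autoplot.characteristic_ratio <- function(object, ...) {
  ggplot(object, aes(x = .data$n, y = .data$C_n)) +
    geom_line() + scale_x_log10() +
    labs(x = "n", y = "C_n",
         title = sprintf("C_inf = %.2f", attr(object, "C_inf"))) + theme_bw()
}

#' Plot the IBI convergence history
#'
#' @param object an `ibi_state`.
#' @param ... ignored.
#' @method autoplot ibi_state
#' @export
autoplot.ibi_state <- function(object, ...) {
  ggplot(object$log, aes(x = .data$iteration, y = .data$mean_norm)) +
    geom_line() + geom_point() +
    labs(x = "evaluation", y = "mean convergence norm") + theme_bw()
}

#' @importFrom ggplot2 .data
NULL
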