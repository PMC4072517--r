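#' Environment and swimming parameters
#'
#' A static exponential attractant field `L(x) = L0 * exp(g * x)` along the
#' first spatial axis, together with the cell's swimming speed and
#' rotational diffusion constant. `d` is the spatial dimensionality used by
#' the analytic one-dimensional reduction (runs up/down the gradient with a
#' reorientation jump rate `(d-1) * Dr`; drift rescaled by `1/d`).
#'
#' @param L0 ligand concentration at the origin (µM).
#' @param g gradient inverse length scale (µm^-1); `g = 0` is a uniform
#'   environment.
#' @param v swimming speed during runs (µm/s).
#' @param Dr rotational diffusion constant (rad^2/s).
#' @param d spatial dimensionality for the analytic mapping (2 or 3).
#' @return an object of class `environment_params`.
#' @export
#' @examples
#' environment_params(g = 1 / 5000)  # shallow gradient
environment_params <- function(L0 = 200, g = 0, v = 20, Dr = 0.062, d = 3) {
  stopifnot(L0 > 0, v > 0, Dr >= 0, d %in% c(2, 3), g >= 0)
  structure(list(L0 = L0, g = g, v = v, Dr = Dr, d = d),
            class = "environment_params")
}

#' @export
print.environment_params <- function(x, ...) {
  cat("<environment_params>",
      sprintf("L0 = %g uM, g = %g /um%s", x$L0, x$g,
              if (x$g > 0) sprintf(" (1/g = %g um)", 1 / x$g) else ""),
      sprintf("v = %g um/s, Dr = %g rad^2/s, d = %d", x$v, x$Dr, x$d),
      sep = "\n")
  invisible(x)
}

#' Cell phenotype
#'
#' A phenotype is the pair (adapted CheY-P concentration `Y0`, receptor
#' adaptation time `tau`), the unit of all parameter sweeps. Derived
#' quantities: the adapted free energy `F0 = log(alpha/Y0 - 1)` and the
#' adapted tumble bias `TB0` (non-adapted motor CW bias at `Y0`, or the
#' adapted-motor steady-state bias when `mp$adapt` is on).
#'
#' @param Y0 adapted CheY-P concentration (µM), in `(0, alpha)`.
#' @param tau receptor adaptation time (s).
#' @param p a [pathway_params()] object (its `tau` is overridden).
#' @param mp a [motor_params()] object used to derive `TB0`.
#' @return an object of class `phenotype`.
#' @export
#' @examples
#' phenotype(Y0 = 2.4, tau = 10)
phenotype <- function(Y0, tau, p = pathway_params(), mp = motor_params()) {
  stopifnot(tau > 0)
  F0 <- f0_of_y0(Y0, p)  # validates 0 < Y0 < alpha
  TB0 <- if (mp$adapt) flim_steady(Y0, mp)$CW else cw_bias(Y0, mp)
  p$tau <- tau
  structure(list(Y0 = Y0, tau = tau, F0 = F0, TB0 = TB0, pathway = p),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("<phenotype> Y0 = %g uM, tau = %g s (F0 = %.4g, TB0 = %.4g)\n",
              x$Y0, x$tau, x$F0, x$TB0))
  invisible(x)
}
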