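#' Flagellar-motor parameters
#'
#' The motor is a bistable two-state system (CCW = run, CW = tumble) with
#' switching frequency `omega` and free-energy difference
#' `dG(Y) = eps2/2 - eps3 * Y/(Y + K)` between the two rotational states.
#' `eps2` sets the basal switching at `Y = 0`, `eps3` the cooperativity of
#' the CheY-P response and `K` the CheY-P/FliM binding constant. The default
#' values place the CW-bias half-maximum at `K = 3.06` µM with an effective
#' Hill coefficient of 20.
#'
#' Slow FliM-ring remodelling (motor adaptation) is modelled as a
#' continuous binding/unbinding process for the FliM copy number `n`,
#' bounded by `n1 <= n <= n2`, with the motor cooperativity following
#' `eps3(n) = eps3_0 + eps3_1 * (n - n0)`.
#'
#' @param omega motor switching frequency (s^-1).
#' @param eps2,eps3 non-dimensional motor energy constants.
#' @param K CheY-P/FliM binding constant (µM).
#' @param adapt logical; enable FliM-ring adaptation.
#' @param k_on,k_off FliM exchange rate constants (s^-1): `k_off` scales
#'   the CCW-driven recruitment (binding) term and `k_on` the CW-driven
#'   release term, so the ring adapts the motor towards a CW bias of
#'   `k_off/(k_on + k_off)` (about 0.2 with the defaults).
#' @param n1,n2 minimum/maximum FliM ring size.
#' @param n0 pre-stimulus FliM copy number.
#' @param dn effective half-max copy-number scale of the saturating
#'   binding/unbinding factors.
#' @param eps3_0,eps3_1 intercept and slope of `eps3(n)`.
#' @return an object of class `motor_params`.
#' @export
motor_params <- function(omega = 1.3, eps2 = 80, eps3 = 80, K = 3.06,
                         adapt = FALSE, k_on = 0.025, k_off = 0.0063,
                         n1 = 34, n2 = 44, n0 = 36, dn = 4.16,
                         eps3_0 = 80, eps3_1 = 1.96) {
  stopifnot(omega > 0, K > 0, n1 < n0, n0 < n2, dn > 0,
            k_on > 0, k_off > 0)
  structure(list(omega = omega, eps2 = eps2, eps3 = eps3, K = K,
                 adapt = isTRUE(adapt), k_on = k_on, k_off = k_off,
                 n1 = n1, n2 = n2, n0 = n0, dn = dn,
                 eps3_0 = eps3_0, eps3_1 = eps3_1),
            class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("<motor_params>",
      sprintf("omega = %g /s, eps2 = %g, eps3 = %g, K = %g uM",
              x$omega, x$eps2, x$eps3, x$K),
      sprintf("FliM adaptation: %s (k_on = %g, k_off = %g /s; n in [%g, %g], n0 = %g)",
              if (x$adapt) "on" else "off", x$k_on, x$k_off, x$n1, x$n2,
              x$n0), sep = "\n")
  invisible(x)
}

# eps3 as a function of the FliM copy number
eps3_of_n <- function(n, mp) mp$eps3_0 + mp$eps3_1 * (n - mp$n0)

#' Motor free-energy difference between CW and CCW states
#'
#' `dG(Y) = eps2/2 - eps3 * Y/(Y + K)`: monotone decreasing in CheY-P, so
#' increasing CheY-P biases the motor towards CW (tumble).
#'
#' @param Y CheY-P concentration (µM), `>= 0`.
#' @param eps2,eps3 motor energy constants.
#' @param K binding constant (µM).
#' @return `dG`, vectorized over `Y`.
#' @export
motor_free_energy <- function(Y, eps2 = 80, eps3 = 80, K = 3.06) {
  if (any(Y < 0)) stop("CheY-P concentration must be >= 0")
  eps2 / 2 - eps3 * Y / (Y + K)
}

#' Motor clockwise bias
#'
#' `CW(Y) = 1 / (1 + exp(dG(Y)))`, the stationary probability of the CW
#' (tumbling) state. In the single-motor model the cell tumble bias equals
#' the motor CW bias.
#'
#' @inheritParams motor_free_energy
#' @param mp a [motor_params()] object.
#' @param eps3 optional override of the cooperativity constant (used when
#'   the FliM ring has remodelled); defaults to `mp$eps3`.
#' @return CW bias in `(0, 1)`, vectorized over `Y`.
#' @export
cw_bias <- function(Y, mp = motor_params(), eps3 = NULL) {
  if (is.null(eps3)) eps3 <- mp$eps3
  1 / (1 + exp(motor_free_energy(Y, mp$eps2, eps3, mp$K)))
}

#' Run/tumble switching rates
#'
#' Symmetric Arrhenius split of the two-state kinetics:
#' `lambda_R = omega * exp(-dG/2)` (run -> tumble) and
#' `lambda_T = omega * exp(+dG/2)` (tumble -> run). The product
#' `lambda_R * lambda_T = omega^2` is exact, and the stationary CW
#' occupancy `lambda_R / (lambda_R + lambda_T)` equals [cw_bias()].
#'
#' @inheritParams cw_bias
#' @return a list with vectors `lambda_R` and `lambda_T` (s^-1).
#' @export
switching_rates <- function(Y, mp = motor_params(), eps3 = NULL) {
  if (is.null(eps3)) eps3 <- mp$eps3
  dG <- motor_free_energy(Y, mp$eps2, eps3, mp$K)
  list(lambda_R = mp$omega * exp(-dG / 2),
       lambda_T = mp$omega * exp(dG / 2))
}

# saturating binding/unbinding occupancy factors for the FliM ring
flim_bind_factor <- function(n, mp) (mp$n2 - n) / ((mp$n2 - n) + mp$dn)
flim_unbind_factor <- function(n, mp) (n - mp$n1) / ((n - mp$n1) + mp$dn)

# dn/dt of the FliM ring at clockwise bias CW. CCW rotation recruits FliM
# at rate constant k_off (the binding rate in the source calibration),
# CW rotation releases it at k_on; the ring therefore adapts towards the
# CW bias k_off/(k_on + k_off) ~ 0.2 where the two terms balance.
flim_rate <- function(n, CW, mp) {
  mp$k_off * (1 - CW) * flim_bind_factor(n, mp) -
    mp$k_on * CW * flim_unbind_factor(n, mp)
}

#' Advance the FliM ring by one Euler step
#'
#' FliM recruitment is promoted by CCW rotation and loss by CW rotation:
#' `dn/dt = k_off*(1-CW)*(n2-n)/((n2-n)+dn) - k_on*CW*(n-n1)/((n-n1)+dn)`.
#' The saturating factors pin `n` inside `[n1, n2]`. Because
#' `eps3(n)` increases with `n`, this is a negative feedback: a persistent
#' drop in CW bias grows the ring, re-sensitizing the motor at lower
#' CheY-P, so the CW bias partially adapts towards
#' `k_off/(k_on + k_off)`.
#'
#' @param state list with `n` (FliM copy number).
#' @param CW current clockwise bias (or instantaneous CW indicator).
#' @param dt time step (s).
#' @param mp a [motor_params()] object.
#' @return the updated state with fields `n` and `eps3_eff`.
#' @export
flim_step <- function(state, CW, dt, mp = motor_params()) {
  stopifnot(dt > 0)
  n_new <- state$n + dt * flim_rate(state$n, CW, mp)
  n_new <- min(max(n_new, mp$n1), mp$n2)
  state$n <- n_new
  state$eps3_eff <- eps3_of_n(n_new, mp)
  state
}

#' Quasi-steady FliM ring size and adapted CW-bias curve
#'
#' At fixed CheY-P the ring relaxes to the joint root of `dn/dt = 0` and
#' `CW = cw_bias(Y; eps3(n))`. `flim_steady()` returns that root for one
#' `Y`; [adapted_cw_curve()] evaluates it over a grid, yielding the CW-bias
#' response of the *adapted* motor, which is shallower than the
#' fixed-`eps3` response because the ring remodels against persistent
#' changes in CW bias.
#'
#' @param Y CheY-P concentration (µM).
#' @param mp a [motor_params()] object.
#' @return `flim_steady()`: list with `n`, `eps3`, `CW` and logical
#'   `pinned` (root at a ring-size boundary).
#' @export
flim_steady <- function(Y, mp = motor_params()) {
  gfun <- function(n) flim_rate(n, cw_bias(Y, mp, eps3 = eps3_of_n(n, mp)), mp)
  g1 <- gfun(mp$n1)
  g2 <- gfun(mp$n2)
  # binding vanishes at n2 and unbinding at n1, so g1 >= 0 >= g2 always
  if (g1 <= 0) {
    n_star <- mp$n1
  } else if (g2 >= 0) {
    n_star <- mp$n2
  } else {
    n_star <- uniroot(gfun, c(mp$n1, mp$n2), tol = 1e-10)$root
  }
  eps3 <- eps3_of_n(n_star, mp)
  list(n = n_star, eps3 = eps3, CW = cw_bias(Y, mp, eps3 = eps3),
       pinned = n_star <= mp$n1 + 1e-9 || n_star >= mp$n2 - 1e-9)
}

#' @rdname flim_steady
#' @param Y_grid grid of CheY-P concentrations (µM).
#' @return `adapted_cw_curve()`: data.frame with columns `Y`, `CW`, `n`,
#'   `eps3`, `pinned`.
#' @export
adapted_cw_curve <- function(Y_grid, mp = motor_params()) {
  res <- lapply(Y_grid, flim_steady, mp = mp)
  data.frame(Y = Y_grid,
             CW = vapply(res, `[[`, numeric(1), "CW"),
             n = vapply(res, `[[`, numeric(1), "n"),
             eps3 = vapply(res, `[[`, numeric(1), "eps3"),
             pinned = vapply(res, `[[`, logical(1), "pinned"))
}

#' Effective Hill coefficient of a response curve
#'
#' Computed at the half-maximum from the local slope,
#' `n_H = 4 * Y_half * dCW/dY` evaluated where `CW = max(CW)/2` — the
#' identity satisfied exactly by a Hill function. A least-squares Hill fit
#' is returned alongside for comparison.
#'
#' @param Y,CW samples of a monotone response curve spanning both sides of
#'   its half-maximum.
#' @return list with `n_H` (slope method), `Y_half`, and `n_H_fit` /
#'   `K_fit` from the least-squares Hill fit.
#' @export
hill_coefficient <- function(Y, CW) {
  stopifnot(length(Y) == length(CW), length(Y) >= 5)
  o <- order(Y)
  Y <- Y[o]; CW <- CW[o]
  half <- max(CW) / 2
  if (min(CW) > half || max(CW) < half)
    stop("response curve does not span its half-maximum")
  sf <- splinefun(Y, CW, method = "hyman")
  Y_half <- uniroot(function(y) sf(y) - half, range(Y), tol = 1e-10)$root
  n_H <- 4 * Y_half * sf(Y_half, deriv = 1) / max(CW)
  # least-squares Hill fit CW = top * Y^n / (Y^n + K^n)
  top <- max(CW)
  obj <- function(par) {
    nh <- exp(par[1]); K <- exp(par[2])
    sum((CW - top * Y^nh / (Y^nh + K^nh))^2)
  }
  fit <- optim(c(log(max(n_H, 1)), log(Y_half)), obj)
  list(n_H = n_H, Y_half = Y_half,
       n_H_fit = exp(fit$par[1]), K_fit = exp(fit$par[2]))
}
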