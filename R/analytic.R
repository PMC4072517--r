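#' Operating point of the pathway-motor system
#'
#' Collects the quantities entering the linearized drift theory, all
#' evaluated at a given operational CheY-P concentration: switching rates,
#' the expected run duration along a direction
#' `tauR = 1/((d-1)*Dr + lambda_R)` (runs along a direction are terminated
#' by a tumble or by rotational diffusion), the expected tumble duration
#' `tauT = 1/lambda_T`, the tumble bias, and the sensitivity
#' `G = -d(lambda_R)/dF`, i.e. how strongly a free-energy excursion
#' modulates the tumbling rate.
#'
#' @param Y_op operational CheY-P concentration (µM).
#' @param p a [pathway_params()] object.
#' @param env an [environment_params()] object.
#' @param mp a [motor_params()] object.
#' @param eps3 optional motor cooperativity override (e.g. the quasi-steady
#'   FliM-adapted value).
#' @return an object of class `operating_point` (list with `Y_op`, `F_op`,
#'   `lamR`, `lamT`, `tauR`, `tauT`, `TB`, `G`). All fields are vectorized
#'   over `Y_op`.
#' @export
operating_point <- function(Y_op, p = pathway_params(),
                            env = environment_params(),
                            mp = motor_params(), eps3 = NULL) {
  if (is.null(eps3)) eps3 <- mp$eps3
  F_op <- f0_of_y0(Y_op, p)
  rates <- switching_rates(Y_op, mp, eps3 = eps3)
  lamR <- rates$lambda_R
  lamT <- rates$lambda_T
  tauR <- 1 / ((env$d - 1) * env$Dr + lamR)
  # dY/dF = -Y(1 - Y/alpha); d(dG)/dY = -eps3*K/(Y+K)^2
  # G = -dlamR/dF = (lamR/2) * eps3*K/(Y+K)^2 * Y*(1 - Y/alpha) > 0
  G <- lamR / 2 * eps3 * mp$K / (Y_op + mp$K)^2 * Y_op * (1 - Y_op / p$alpha)
  structure(list(Y_op = Y_op, F_op = F_op, lamR = lamR, lamT = lamT,
                 tauR = tauR, tauT = 1 / lamT,
                 TB = lamR / (lamR + lamT), G = G, eps3 = eps3),
            class = "operating_point")
}

#' Linearized steady-state drift velocity
#'
#' First-order (shallow-gradient) expansion of the run-and-tumble drift
#' around an operating point:
#' \deqn{V_D = \frac{v}{d}\, f\, G\, \tau_R^2
#'       \frac{\tau\,\tau_R}{\tau+\tau_R} \frac{1}{\tau_R+\tau_T}}
#' where `f = v*N*g` is the constant rate of free-energy change in an
#' exponential gradient, `G` the tumbling-rate sensitivity and
#' `tau*tauR/(tau+tauR)` the exponential-kernel time average of the
#' free-energy excursion over a run. The `1/d` factor maps the
#' one-dimensional two-state theory onto `d`-dimensional swimming. For
#' `tau << tauR` the drift grows linearly in `tau`; for `tau >> tauR` it
#' saturates.
#'
#' @param op an [operating_point()] (fields may be vectors).
#' @param tau receptor adaptation time (s).
#' @param f rate of free-energy change (s^-1); defaults to `v*N*g`.
#' @param env an [environment_params()] object.
#' @param p a [pathway_params()] object (for `N` when `f` is omitted).
#' @return drift velocity (µm/s), vectorized like `op`.
#' @export
drift_linearized <- function(op, tau, env = environment_params(),
                             f = NULL, p = pathway_params()) {
  stopifnot(inherits(op, "operating_point"), tau > 0)
  if (is.null(f)) f <- env$v * p$N * env$g
  kernel <- tau * op$tauR / (tau + op$tauR)
  env$v / env$d * f * op$G * op$tauR^2 * kernel / (op$tauR + op$tauT)
}

#' Expected run duration along a direction (exact hazard integral)
#'
#' The expected duration of a run in direction `s` (+1 up-gradient, -1
#' down, 0 tumbling/immobile), starting from free energy `F_i`, is the
#' survival integral
#' \deqn{\langle t_s\rangle=\int_0^\infty
#'   \exp\Big(-\int_0^t \lambda_R(F(t'))+(d-1)D_r\, dt'\Big) dt}
#' with `F(t)` the closed-form relaxation `F0 + s*f*tau +
#' (F_i - F0 - s*f*tau) * exp(-t/tau)` of the methylation dynamics under a
#' constant free-energy ramp `s*f`. Evaluated by trapezoidal quadrature
#' with Richardson step-halving to a relative tolerance of 1e-5.
#'
#' @param F_i initial free-energy difference.
#' @param s run direction: +1, -1 (or 0 for no signal).
#' @param phen a [phenotype()] object (`F0`, `tau`, pathway constants).
#' @param env an [environment_params()] object.
#' @param mp a [motor_params()] object.
#' @param f free-energy ramp magnitude (s^-1); defaults to `v*N*g`.
#' @param eps3 optional motor cooperativity override.
#' @return expected run duration (s).
#' @export
expected_run_duration <- function(F_i, s, phen, env = environment_params(),
                                  mp = motor_params(), f = NULL,
                                  eps3 = NULL) {
  stopifnot(s %in% c(-1, 0, 1))
  p <- phen$pathway
  if (is.null(f)) f <- env$v * p$N * env$g
  if (is.null(eps3)) eps3 <- mp$eps3
  tau <- phen$tau
  F_inf <- phen$F0 + s * f * tau
  lam_of_F <- function(F) {
    Y <- chey_p(F, p)
    mp$omega * exp(-motor_free_energy(Y, mp$eps2, eps3, mp$K) / 2) +
      (env$d - 1) * env$Dr
  }
  if (lam_of_F(F_inf) < 1e-10 && lam_of_F(F_i) < 1e-10)
    stop("run termination rate vanishes; expected duration diverges")
  quad <- function(dt) {
    t_max <- 0
    hazard <- 0
    # extend until the cumulative hazard makes the survival negligible
    total <- 0
    t0 <- 0
    repeat {
      t_max <- t0 + max(200 * dt, 5 / lam_of_F(F_inf + (F_i - F_inf) *
                                                 exp(-t0 / tau)))
      tt <- seq(t0, t_max, by = dt)
      lam <- lam_of_F(F_inf + (F_i - F_inf) * exp(-tt / tau))
      cumhaz <- hazard + c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
      surv <- exp(-cumhaz)
      total <- total + sum((surv[-1] + surv[-length(surv)]) / 2 * dt)
      if (cumhaz[length(cumhaz)] > 30) break
      hazard <- cumhaz[length(cumhaz)]
      t0 <- t_max
    }
    total
  }
  dt <- min(tau, 1 / lam_of_F(F_i), 1 / lam_of_F(F_inf)) / 100
  est <- quad(dt)
  repeat {
    dt <- dt / 2
    est2 <- quad(dt)
    if (abs(est2 - est) <= 1e-5 * abs(est2)) break
    est <- est2
    if (dt < 1e-7) break
  }
  est2
}

#' Exact (non-linearized) drift velocity from expected run durations
#'
#' Composes the two-state picture directly: runs up and down the gradient
#' with expected durations from [expected_run_duration()] starting at the
#' operating free energy, separated by tumbles of expected duration
#' `1/lambda_T`:
#' \deqn{V_D = \frac{v}{d}\,
#'   \frac{\langle t_{up}\rangle-\langle t_{down}\rangle}
#'        {\langle t_{up}\rangle+\langle t_{down}\rangle+2\langle t_T\rangle}}
#' This serves as the numeric oracle for [drift_linearized()]; the two
#' agree in shallow gradients and depart where the linearization fails.
#'
#' @inheritParams expected_run_duration
#' @param Y_op operational CheY-P at which runs start and tumble rates are
#'   evaluated; defaults to the adapted `phen$Y0`.
#' @return drift velocity (µm/s).
#' @export
drift_exact <- function(phen, env = environment_params(),
                        mp = motor_params(), Y_op = phen$Y0, eps3 = NULL) {
  p <- phen$pathway
  F_op <- f0_of_y0(Y_op, p)
  t_up <- expected_run_duration(F_op, +1, phen, env, mp, eps3 = eps3)
  t_dn <- expected_run_duration(F_op, -1, phen, env, mp, eps3 = eps3)
  lamT <- switching_rates(Y_op, mp, eps3 = eps3)$lambda_T
  env$v / env$d * (t_up - t_dn) / (t_up + t_dn + 2 / lamT)
}

#' Behavioral feedback line
#'
#' A population drifting up an exponential gradient at velocity `V_D`
#' experiences an average exponential ramp of attractant at rate
#' `g * V_D`, shifting the quasi-steady free energy to
#' `F_m = F0 + tau * N * g * V_D` and hence the operational CheY-P below
#' its adapted value. The feedback strength grows with adaptation time,
#' receptor gain, and gradient steepness.
#'
#' @param V_D drift velocity (µm/s); vectorized.
#' @param phen a [phenotype()] object.
#' @param env an [environment_params()] object.
#' @return list with `F_m` and `Y_m` (µM).
#' @export
feedback_line <- function(V_D, phen, env = environment_params()) {
  p <- phen$pathway
  F_m <- phen$F0 + phen$tau * p$N * env$g * V_D
  list(F_m = F_m, Y_m = chey_p(F_m, p))
}

# drift velocity evaluated with the operating point moved to each Y_m
# ("subscript 0 -> m"); eps3 may be a vector matched to Y_grid
drift_curve_values <- function(Y_grid, phen, env, mp, eps3 = NULL) {
  op <- operating_point(Y_grid, phen$pathway, env, mp, eps3 = eps3)
  drift_linearized(op, phen$tau, env, p = phen$pathway)
}

#' Drift-velocity curve over operational CheY-P
#'
#' Evaluates the linearized drift with the operating point placed at each
#' `Y_m` of a grid (all rates and sensitivities re-evaluated at `Y_m`).
#' With `motor_adapt = TRUE` the motor cooperativity is first replaced by
#' its quasi-steady FliM-adapted value `eps3(Y_m)` from [flim_steady()].
#'
#' @param Y_grid operational CheY-P grid (µM).
#' @inheritParams feedback_line
#' @param mp a [motor_params()] object.
#' @param motor_adapt logical; default follows `mp$adapt`.
#' @return data.frame with `Y_m`, `V_D`, and `eps3` used at each point.
#' @export
drift_curve <- function(Y_grid, phen, env = environment_params(),
                        mp = motor_params(), motor_adapt = mp$adapt) {
  eps3 <- if (motor_adapt) {
    vapply(Y_grid, function(y) flim_steady(y, mp)$eps3, numeric(1))
  } else rep(mp$eps3, length(Y_grid))
  data.frame(Y_m = Y_grid,
             V_D = drift_curve_values(Y_grid, phen, env, mp, eps3 = eps3),
             eps3 = eps3)
}

#' @rdname drift_curve
#' @details `motor_adapted_drift()` is the explicit motor-adaptation
#'   variant: for each `Y_m` it solves the joint quasi-steady state of the
#'   FliM ring and the motor response, then evaluates the drift with the
#'   resulting `eps3(Y_m)`.
#' @export
motor_adapted_drift <- function(Y_grid, phen, env = environment_params(),
                                mp = motor_params()) {
  drift_curve(Y_grid, phen, env, mp, motor_adapt = TRUE)
}

#' Fixed points of the drift/feedback system
#'
#' The steady states of a phenotype in an exponential gradient are the
#' intersections of the drift curve `V_D(Y_m)` ([drift_curve()]) with the
#' behavioral feedback line `V_D = (F(Y_m) - F0) / (tau*N*g)`
#' (inverse of [feedback_line()]). Roots are bracketed by sign changes of
#' the residual on a fine grid and refined by bisection; stability follows
#' from the mean-field free-energy dynamics
#' `dF/dt = (F0 - F)/tau + N*g*V_D(Y(F))`: a root is stable when the
#' residual (as a function of `Y_m`) crosses zero from below.
#' Generically there are one or three fixed points; three-root phenotypes
#' are bistable, with the high-`Y_m`, near-zero-drift stable state being
#' the chemotactic "trap".
#'
#' @inheritParams drift_curve
#' @param Y_range range of operational CheY-P to scan (µM).
#' @param dY grid spacing (µM); refined automatically by bisection.
#' @return data.frame of class `fixed_points` with columns `Y_m`, `V_D`,
#'   `stable`; attribute `bistable`.
#' @export
fixed_points <- function(phen, env = environment_params(),
                         mp = motor_params(), motor_adapt = mp$adapt,
                         Y_range = c(0.2, NA), dY = 0.0025) {
  p <- phen$pathway
  if (is.na(Y_range[2])) Y_range[2] <- p$alpha - 0.05
  stopifnot(env$g > 0)
  tNg <- phen$tau * p$N * env$g
  Y <- seq(Y_range[1], Y_range[2], by = dY)
  eps3_fun <- if (motor_adapt) {
    eps3_adapted_fun(mp, Y_range = Y_range)
  } else function(y) rep(mp$eps3, length(y))
  resid <- function(y) {
    drift_curve_values(y, phen, env, mp, eps3 = eps3_fun(y)) -
      (f0_of_y0(y, p) - phen$F0) / tNg
  }
  r <- resid(Y)
  idx <- which(r[-1] * r[-length(r)] < 0)
  roots <- lapply(idx, function(i) {
    root <- uniroot(resid, c(Y[i], Y[i + 1]), tol = 1e-9)$root
    # residual crossing - -> + (in Y) is stable for the F-dynamics
    stable <- r[i] < 0
    v <- drift_curve_values(root, phen, env, mp, eps3 = eps3_fun(root))
    data.frame(Y_m = root, V_D = v, stable = stable)
  })
  out <- if (length(roots)) do.call(rbind, roots) else
    data.frame(Y_m = numeric(0), V_D = numeric(0), stable = logical(0))
  attr(out, "bistable") <- sum(out$stable) > 1
  class(out) <- c("fixed_points", class(out))
  out
}

# cached interpolator for the quasi-steady FliM-adapted eps3(Y)
eps3_adapted_fun <- function(mp, Y_range = c(0.2, 5.8), n_grid = 240) {
  yg <- seq(Y_range[1], Y_range[2], length.out = n_grid)
  e3 <- vapply(yg, function(y) flim_steady(y, mp)$eps3, numeric(1))
  approxfun(yg, e3, rule = 2)
}

#' Steady-state drift velocity of a phenotype
#'
#' Convenience wrapper around [fixed_points()]: returns the drift velocity
#' of the stable fixed point with the largest drift (the fast-drifting
#' state when the system is bistable), together with its `Y_m` and a
#' bistability flag.
#'
#' @inheritParams fixed_points
#' @return list with `V_D`, `Y_m`, `bistable`.
#' @export
steady_drift <- function(phen, env = environment_params(),
                         mp = motor_params(), motor_adapt = mp$adapt) {
  fp <- fixed_points(phen, env, mp, motor_adapt = motor_adapt)
  st <- fp[fp$stable, , drop = FALSE]
  if (!nrow(st)) return(list(V_D = 0, Y_m = phen$Y0, bistable = FALSE))
  i <- which.max(st$V_D)
  list(V_D = st$V_D[i], Y_m = st$Y_m[i], bistable = attr(fp, "bistable"))
}

#' Optimal adapted CheY-P concentration for a given adaptation time
#'
#' Maximizes the steady-state drift velocity (accounting for behavioral
#' feedback, and for motor adaptation when enabled) over the adapted
#' CheY-P concentration `Y0`. Flags when the optimum lies in the bistable
#' region, where the fast state coexists with the chemotactic trap and the
#' theoretical optimum is not reliably accessible.
#'
#' @param tau receptor adaptation time (s).
#' @param env an [environment_params()] object (needs `g > 0`).
#' @param mp a [motor_params()] object.
#' @param p a [pathway_params()] object.
#' @param motor_adapt logical; default follows `mp$adapt`.
#' @param Y0_grid candidate adapted concentrations (µM).
#' @return list with `Y0_opt`, `V_D`, `Y_m` (operational CheY-P at the
#'   optimum) and `bifurcated`.
#' @export
optimal_Y0 <- function(tau, env = environment_params(), mp = motor_params(),
                       p = pathway_params(), motor_adapt = mp$adapt,
                       Y0_grid = seq(1, 4.5, by = 0.02)) {
  pre <- steady_drift_precompute(p, env, mp, motor_adapt)
  best <- list(V_D = -Inf)
  for (y0 in Y0_grid) {
    sd_ <- steady_drift_fast(f0_of_y0(y0, p), tau, pre)
    if (sd_$V_D > best$V_D)
      best <- list(Y0_opt = y0, V_D = sd_$V_D, Y_m = sd_$Y_m,
                   bifurcated = sd_$bistable)
  }
  best
}

# precompute the Y_m-grid quantities shared by all phenotypes of a given
# pathway/motor/environment combination (the motor response, run/tumble
# time scales and sensitivity depend on Y_m only)
steady_drift_precompute <- function(p, env, mp, motor_adapt = mp$adapt,
                                    dY = 0.0025) {
  Y <- seq(0.2, p$alpha - 0.05, by = dY)
  eps3 <- if (motor_adapt) eps3_adapted_fun(mp, range(Y))(Y) else
    rep(mp$eps3, length(Y))
  opg <- operating_point(Y, p, env, mp, eps3 = eps3)
  list(Y = Y, opg = opg, F_vec = opg$F_op, p = p, env = env,
       f = env$v * p$N * env$g,
       base = opg$G * opg$tauR^2 / (opg$tauR + opg$tauT))
}

# fast grid-level fixed-point solve; drift and Y_m linearly interpolated
# at the residual's zero crossings. branch "fastest" returns the stable
# root with the largest drift (the theoretical fast state); "reachable"
# the stable root with the largest Y_m, which is the state the mean-field
# dynamics reach from the adapted initial condition Y_m = Y0 (the trap
# when the system is bistable).
steady_drift_fast <- function(F0, tau, pre,
                              branch = c("fastest", "reachable")) {
  branch <- match.arg(branch)
  kernel <- tau * pre$opg$tauR / (tau + pre$opg$tauR)
  vd <- pre$env$v / pre$env$d * pre$f * pre$base * kernel
  r <- vd - (pre$F_vec - F0) / (tau * pre$p$N * pre$env$g)
  n <- length(r)
  up <- which(r[-1] > 0 & r[-n] < 0)    # stable crossings
  dn <- which(r[-1] < 0 & r[-n] > 0)    # unstable crossings
  if (!length(up)) return(list(V_D = 0, Y_m = NA_real_, bistable = FALSE))
  w <- r[up] / (r[up] - r[up + 1])
  vstar <- (1 - w) * vd[up] + w * vd[up + 1]
  ystar <- (1 - w) * pre$Y[up] + w * pre$Y[up + 1]
  i <- if (branch == "fastest") which.max(vstar) else which.max(ystar)
  list(V_D = vstar[i], Y_m = ystar[i], bistable = length(up) > 1,
       n_stable = length(up), n_unstable = length(dn))
}

#' Chemotaxis coefficient
#'
#' `chi = V_D / g` from the linearized drift at the adapted operating
#' point; in the shallow-gradient (linear-response) regime `chi` is
#' independent of `g` and proportional to the receptor gain `N`.
#'
#' @inheritParams drift_curve
#' @return `chi` in µm^2/s.
#' @export
chemotaxis_coefficient <- function(phen, env = environment_params(),
                                   mp = motor_params()) {
  stopifnot(env$g > 0)
  op <- operating_point(phen$Y0, phen$pathway, env, mp)
  drift_linearized(op, phen$tau, env, p = phen$pathway) / env$g
}

#' Phenotype performance map across gradients
#'
#' Steady-state drift velocity (with behavioral feedback; motor adaptation
#' per `mp$adapt`) on a grid of phenotypes parameterized by adaptation
#' time `tau` and adapted tumble bias `TB0`, for several gradient length
#' scales. The steady state used is the one reachable from the adapted
#' initial condition (bistable phenotypes land in the trap), and each
#' gradient's surface is normalized by that gradient's maximal accessible
#' drift velocity — the reachable-state optimum over the full phenotype
#' space (`Y0` unconstrained), which may lie outside the mapped `TB0`
#' range; the bifurcation bounds it from above. The generalist (maximin)
#' phenotype maximizes the worst-case relative performance across
#' gradients.
#'
#' `TB0` is converted to `Y0` by inverting the CW-bias response of the
#' same motor model used for the map (the FliM-adapted response when
#' `mp$adapt` is on).
#'
#' @param tau_grid adaptation times (s).
#' @param TB0_grid adapted tumble biases.
#' @param gradients vector of inverse length scales `g` (µm^-1).
#' @param p a [pathway_params()] object.
#' @param mp a [motor_params()] object.
#' @param env_template an [environment_params()] giving `L0`, `v`, `Dr`,
#'   `d`; its `g` is replaced by each gradient in turn.
#' @return object of class `phenotype_map`: list with the grids, the `Y0`
#'   conversion, per-gradient absolute and relative drift arrays
#'   (`tau x TB0 x gradient`), and the maximin summary.
#' @export
phenotype_map <- function(tau_grid = exp(seq(log(1), log(30), length.out = 40)),
                          TB0_grid = exp(seq(log(0.01), log(0.4), length.out = 40)),
                          gradients = 1 / c(1000, 2000, 5000),
                          p = pathway_params(), mp = motor_params(adapt = TRUE),
                          env_template = environment_params()) {
  # TB0 -> Y0 through the map's own motor model
  yg <- seq(0.2, p$alpha - 0.2, length.out = 400)
  cw <- if (mp$adapt) adapted_cw_curve(yg, mp)$CW else cw_bias(yg, mp)
  y0_of_tb <- approxfun(cw, yg, rule = 2, ties = "ordered")
  Y0_grid <- y0_of_tb(TB0_grid)

  nt <- length(tau_grid); nb <- length(TB0_grid); ng <- length(gradients)
  V <- array(NA_real_, dim = c(nt, nb, ng),
             dimnames = list(NULL, NULL, paste0("g", seq_len(ng))))
  V_max <- numeric(ng)
  F0_grid <- f0_of_y0(Y0_grid, p)
  F0_free <- f0_of_y0(seq(1, 4.5, by = 0.02), p)
  for (k in seq_len(ng)) {
    env <- env_template
    env$g <- gradients[k]
    pre <- steady_drift_precompute(p, env, mp, motor_adapt = mp$adapt)
    for (i in seq_len(nt)) for (j in seq_len(nb))
      V[i, j, k] <- steady_drift_fast(F0_grid[j], tau_grid[i], pre,
                                      branch = "reachable")$V_D
    # the gradient's maximal accessible drift: optimum of the reachable
    # steady state over the full phenotype space (Y0 free), not just the
    # mapped TB0 range; the bifurcation bounds this maximum from above
    V_max[k] <- max(vapply(tau_grid, function(tv) {
      max(vapply(F0_free, function(F0)
        steady_drift_fast(F0, tv, pre, branch = "reachable")$V_D,
        numeric(1)))
    }, numeric(1)))
    # guard against interpolation-level overshoot of the free-Y0 optimum
    V_max[k] <- max(V_max[k], max(V[, , k]))
  }
  rel <- V
  for (k in seq_len(ng)) rel[, , k] <- V[, , k] / V_max[k]
  worst <- apply(rel, c(1, 2), min)
  imax <- arrayInd(which.max(worst), dim(worst))
  structure(list(tau_grid = tau_grid, TB0_grid = TB0_grid,
                 Y0_grid = Y0_grid, gradients = gradients,
                 V_D = V, V_max = V_max, relative = rel,
                 worst_case = worst,
                 maximin = list(tau = tau_grid[imax[1]],
                                TB0 = TB0_grid[imax[2]],
                                Y0 = Y0_grid[imax[2]],
                                relative = max(worst))),
            class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  m <- x$maximin
  cat("<phenotype_map>",
      sprintf("grid: %d tau x %d TB0 x %d gradients (1/g = %s um)",
              length(x$tau_grid), length(x$TB0_grid), length(x$gradients),
              paste(round(1 / x$gradients), collapse = ", ")),
      sprintf("maximin phenotype: tau = %.3g s, TB0 = %.3g (Y0 = %.3g uM), worst-case relative V_D = %.1f%%",
              m$tau, m$TB0, m$Y0, 100 * m$relative), sep = "\n")
  invisible(x)
}
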