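# Independent oracles used across the test files.

# Gillespie simulation of the two-state (run/tumble) motor at fixed CheY-P:
# alternating exponential holding times. Returns the fraction of time spent
# in the CW (tumble) state.
gillespie_cw_fraction <- function(Y, mp, n_switches = 1e5, seed = 1) {
  set.seed(seed)
  rates <- switching_rates(Y, mp)
  t_run <- sum(rexp(n_switches, rates$lambda_R))
  t_tum <- sum(rexp(n_switches, rates$lambda_T))
  t_tum / (t_run + t_tum)
}

# Euler integration of the receptor free-energy ODE
# dF/dt = (F0 - F)/tau + s*f, the closed-form target of methylation_step.
integrate_F_ode <- function(F_i, F0, tau, s, f, t_end, dt = 1e-3) {
  F <- F_i
  for (i in seq_len(round(t_end / dt))) F <- F + dt * ((F0 - F) / tau + s * f)
  F
}

# forward mean-field map for fixed-point stability: iterate
# dF/dt = (F0 - F)/tau + N*g*V_D(Y(F)) from a perturbed start and report
# the F reached after t_end seconds
forward_F_dynamics <- function(F_start, phen, env, mp, motor_adapt = FALSE,
                               t_end = 2000, dt = 0.5) {
  p <- phen$pathway
  eps3_fun <- if (motor_adapt) {
    chemodrift:::eps3_adapted_fun(mp)
  } else {
    function(y) rep(mp$eps3, length(y))
  }
  F <- F_start
  for (i in seq_len(round(t_end / dt))) {
    Y <- chey_p(F, p)
    op <- operating_point(Y, p, env, mp, eps3 = eps3_fun(Y))
    vd <- drift_linearized(op, phen$tau, env, p = p)
    F <- F + dt * ((phen$F0 - F) / phen$tau + p$N * env$g * vd)
  }
  F
}

# small standard sims reused by several tests (memoised per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
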