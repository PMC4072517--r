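p <- pathway_params()
mp <- motor_params()
env_sh <- environment_params(g = 1 / 5000)
env_st <- environment_params(g = 1 / 1000)

test_that("expected run duration: constant-rate limit and frozen value", {
  phen <- phenotype(2.4, 10, p, mp)
  env0 <- environment_params(g = 0)
  t0 <- expected_run_duration(phen$F0, +1, phen, env0, mp)
  lamR <- switching_rates(2.4, mp)$lambda_R
  expect_equal(t0, 1 / (lamR + 2 * env0$Dr), tolerance = 1e-4)
  expect_equal(t0, 4.17, tolerance = 0.01)     # ~4.2 s at the operating point
})

test_that("runs up the gradient outlast runs down, for any phenotype and ramp", {
  for (Y0 in c(1.8, 2.4, 3.0)) for (f in c(0.02, 0.12)) {
    phen <- phenotype(Y0, 10, p, mp)
    up <- expected_run_duration(phen$F0, +1, phen, env_st, mp, f = f)
    dn <- expected_run_duration(phen$F0, -1, phen, env_st, mp, f = f)
    expect_gt(up, dn)
  }
})

test_that("exact drift: zero at zero gradient, positive up-gradient, near linearized", {
  phen <- phenotype(2.4, 10, p, mp)
  expect_equal(drift_exact(phen, environment_params(g = 0), mp), 0,
               tolerance = 1e-10)
  expect_gt(drift_exact(phen, env_sh, mp), 0)
  # mutual oracle across the sweep range (absolute floor where V ~ 0)
  for (Y0 in c(1.5, 2.0, 2.4, 3.0, 3.5)) {
    phen <- phenotype(Y0, 10, p, mp)
    de <- drift_exact(phen, env_sh, mp)
    dl <- drift_linearized(operating_point(Y0, p, env_sh, mp), 10, env_sh,
                           p = p)
    expect_lt(abs(dl - de), max(0.1 * de, 0.01))
  }
})

test_that("linearized drift: linear onset in tau, saturation, shallow optimum", {
  op <- operating_point(2.4, p, env_sh, mp)
  v1 <- drift_linearized(op, 1e-3, env_sh, p = p)
  v2 <- drift_linearized(op, 2e-3, env_sh, p = p)
  expect_equal(v2 / v1, 2, tolerance = 1e-3)          # linear for tau << tauR
  v5 <- drift_linearized(op, 1e5, env_sh, p = p)
  v6 <- drift_linearized(op, 1e6, env_sh, p = p)
  expect_equal(v6 / v5, 1, tolerance = 1e-3)          # saturation for tau >> tauR
  y0 <- seq(1, 4, by = 0.01)
  vd <- drift_linearized(operating_point(y0, p, env_sh, mp), 10, env_sh, p = p)
  expect_equal(y0[which.max(vd)], 2.4, tolerance = 0.1)
})

test_that("feedback line: intercept at Y0, stated deviation, slope ~ 1/tau", {
  phen <- phenotype(2.7, 30, p, mp)
  expect_equal(feedback_line(0, phen, env_st)$Y_m, 2.7)
  fl <- feedback_line(4, phen, env_st)
  expect_equal(fl$F_m - phen$F0, 0.72)                # tau*N*g*V = 30*6*1e-3*4
  # doubling tau doubles the free-energy deviation per unit drift
  phen2 <- phenotype(2.7, 60, p, mp)
  expect_equal(feedback_line(4, phen2, env_st)$F_m - phen2$F0, 1.44)
})

test_that("fixed points: counts, residuals, and stability against forward dynamics", {
  fp1 <- fixed_points(phenotype(2.7, 5, p, mp), env_st, mp)
  expect_equal(nrow(fp1), 1)
  expect_true(fp1$stable)
  fp3 <- fixed_points(phenotype(3.5, 30, p, mp), env_st, mp)
  expect_equal(nrow(fp3), 3)
  expect_equal(fp3$stable, c(TRUE, FALSE, TRUE))
  expect_true(attr(fp3, "bistable"))
  # residual: every root lies on both curves
  phen <- phenotype(3.5, 30, p, mp)
  for (i in seq_len(3)) {
    vd <- drift_linearized(operating_point(fp3$Y_m[i], p, env_st, mp), 30,
                           env_st, p = p)
    vfb <- (f0_of_y0(fp3$Y_m[i], p) - phen$F0) / (30 * p$N * env_st$g)
    expect_lt(abs(vd - vfb), 1e-6)
  }
  # stability labels agree with forward integration of the mean-field F
  for (i in c(1, 3)) {   # stable roots attract
    F_star <- f0_of_y0(fp3$Y_m[i], p)
    for (dF in c(-0.02, 0.02)) {
      F_end <- forward_F_dynamics(F_star + dF, phen, env_st, mp)
      expect_equal(F_end, F_star, tolerance = 1e-3)
    }
  }
  # the unstable root repels towards its neighbours
  F_u <- f0_of_y0(fp3$Y_m[2], p)
  expect_lt(forward_F_dynamics(F_u - 0.05, phen, env_st, mp),
            F_u - 0.05)  # flows to lower F (higher Y_m): the trap side
  expect_gt(forward_F_dynamics(F_u + 0.05, phen, env_st, mp),
            F_u + 0.05)  # flows to higher F (lower Y_m): the fast side
})

test_that("scanning Y0 at tau = 30 in the steep gradient crosses 1 -> 3 -> 1 roots", {
  counts <- vapply(seq(2.6, 5.4, by = 0.2), function(y0)
    nrow(fixed_points(phenotype(y0, 30, p, mp), env_st, mp)), integer(1))
  expect_equal(counts[1], 1)
  expect_equal(counts[length(counts)], 1)
  expect_true(any(counts == 3))
  # the bistable window contains the trap phenotype Y0 = 3.5
  expect_equal(nrow(fixed_points(phenotype(3.5, 30, p, mp), env_st, mp)), 3)
})

test_that("motor-adapted drift reshapes the curve and shifts the optimum down", {
  mpa <- motor_params(adapt = TRUE)
  phen <- phenotype(2.4, 10, p, mp)
  Y <- seq(0.8, 4.5, by = 0.02)
  plain <- drift_curve(Y, phen, env_sh, mp, motor_adapt = FALSE)
  adapted <- motor_adapted_drift(Y, phen, env_sh, mpa)
  expect_lt(Y[which.max(adapted$V_D)], Y[which.max(plain$V_D)])
  # reshaping is strongest at high CheY-P (adaptation rescues tumbling cells)
  hiY <- Y > 3
  expect_gt(mean(adapted$V_D[hiY]), mean(plain$V_D[hiY]))
  # without ring remodelling the curves coincide
  frozen <- drift_curve(Y, phen, env_sh, mpa, motor_adapt = FALSE)
  expect_equal(frozen$V_D, plain$V_D)
})

test_that("motor adaptation collapses the trap to a single stable state", {
  mpa <- motor_params(adapt = TRUE)
  fp <- fixed_points(phenotype(3.5, 30, p, mpa), env_st, mpa,
                     motor_adapt = TRUE)
  expect_equal(sum(fp$stable), 1)
})

test_that("chemotaxis coefficient: gradient-independent, proportional to N, vanishing with tau", {
  phen <- phenotype(2.4, 10, p, mp)
  chi1 <- chemotaxis_coefficient(phen, environment_params(g = 1 / 5000), mp)
  chi2 <- chemotaxis_coefficient(phen, environment_params(g = 1 / 10000), mp)
  expect_equal(chi1 / chi2, 1, tolerance = 0.02)
  p12 <- pathway_params(N = 12)
  chi_N <- chemotaxis_coefficient(phenotype(2.4, 10, p12, mp), env_sh, mp)
  expect_equal(chi_N / chi1, 2, tolerance = 1e-6)
  phen0 <- phenotype(2.4, 1e-4, p, mp)
  expect_lt(chemotaxis_coefficient(phen0, env_sh, mp), 1e-3 * chi1)
})

test_that("optimal Y0: flat in tau for shallow gradients, common optimal Y_m", {
  opts <- lapply(c(5, 10, 30), optimal_Y0, env = env_sh, mp = mp, p = p,
                 motor_adapt = FALSE)
  y0s <- vapply(opts, `[[`, numeric(1), "Y0_opt")
  expect_lt(diff(range(y0s)), 0.25)
  # the optimal operational concentration is shared across gradients
  o_st <- optimal_Y0(10, env_st, mp, p, motor_adapt = FALSE)
  o_sh <- opts[[2]]
  expect_equal(o_st$Y_m, o_sh$Y_m, tolerance = 0.1)
  # steeper gradients need a higher adapted concentration
  expect_gt(o_st$Y0_opt, o_sh$Y0_opt)
})

test_that("phenotype map: normalized surfaces, trade-off orientation, maximin", {
  pm <- phenotype_map(tau_grid = exp(seq(log(1), log(30), length.out = 14)),
                      TB0_grid = exp(seq(log(0.01), log(0.4), length.out = 14)))
  expect_true(all(pm$relative >= 0 & pm$relative <= 1 + 1e-9))
  expect_true(all(pm$V_max > 0))
  # worst-case is the minimum across gradients at every phenotype
  expect_equal(pm$worst_case, apply(pm$relative, c(1, 2), min))
  # steep-gradient optima: shorter tau, higher TB0 than shallow optima
  i_st <- arrayInd(which.max(pm$relative[, , 1]), dim(pm$worst_case))
  i_sh <- arrayInd(which.max(pm$relative[, , 3]), dim(pm$worst_case))
  expect_lt(pm$tau_grid[i_st[1]], pm$tau_grid[i_sh[1]])
  expect_gt(pm$TB0_grid[i_st[2]], pm$TB0_grid[i_sh[2]])
  # the maximin value is attained on the grid
  expect_equal(max(pm$worst_case), pm$maximin$relative)
})
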