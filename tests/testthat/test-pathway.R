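p <- pathway_params()

test_that("free energy has the MWC structure: offset, methylation, ligand", {
  # ligand term vanishes at L = 0; defaults give eps0 + eps1*6 = 0
  expect_equal(free_energy(6, 0, p), 0)
  # linear in m with slope eps1
  m <- c(0, 10, 20, 48)
  expect_equal(diff(free_energy(m, 123, p)) / diff(m),
               rep(p$eps1, 3))
  # full ligand span is N*log(Ka/Ki), approached numerically at large L
  dF <- free_energy(6, 1e9, p) - free_energy(6, 0, p)
  expect_equal(dF, p$N * log(p$Ka_uM / p$Ki_uM), tolerance = 1e-4)
  expect_equal(p$N * log(p$Ka_uM / p$Ki_uM), 30.62, tolerance = 1e-3)
  # strictly increasing in L
  L <- c(0, 1, 10, 100, 1000, 1e4)
  expect_true(all(diff(free_energy(6, L, p)) > 0))
  expect_error(free_energy(6, -1, p), "L must be >= 0")
  expect_error(free_energy(60, 10, p), "methylation")
})

test_that("chey_p and f0_of_y0 are mutually inverse and bounded", {
  expect_equal(chey_p(0, p), 3)                 # alpha/2
  expect_equal(f0_of_y0(2.4, p), log(1.5))
  for (y in c(0.5, 2.4, 3.5))
    expect_equal(chey_p(f0_of_y0(y, p), p), y)
  Fg <- seq(-10, 10, by = 0.5)
  Y <- chey_p(Fg, p)
  expect_true(all(Y > 0 & Y < p$alpha))
  expect_true(all(diff(Y) < 0))                 # decreasing in F
  expect_error(f0_of_y0(7, p), "alpha = 6")
  expect_error(f0_of_y0(0, p), "alpha")
})

test_that("adapted methylation solves free_energy(m, L) = F0, clamped", {
  expect_equal(as.numeric(adapted_methylation(0, 0, p)), 6)
  # closed form at background L0 = 200 uM for Y0 = 3 (F0 = 0)
  m <- adapted_methylation(200, 0, p)
  expect_equal(as.numeric(m),
               6 + p$N * log((1 + 200 / 18.2) / (1 + 200 / 3000)))
  expect_equal(free_energy(as.numeric(m), 200, p), 0, tolerance = 1e-12)
  # root-finding cross-check
  root <- uniroot(function(mm) free_energy(mm, 200, p), c(0, 48),
                  tol = 1e-10)$root
  expect_equal(as.numeric(m), root, tolerance = 1e-6)
  # demanding F0 far above the accessible range clamps at 0 with a flag
  m0 <- adapted_methylation(0, 60, p)
  expect_equal(as.numeric(m0), 0)
  expect_true(attr(m0, "clamped"))
  expect_false(attr(m, "clamped"))
})

test_that("methylation dynamics adapt precisely at constant ligand", {
  # F = F0 is a fixed point
  st <- list(m = 6, F0 = 0)
  expect_equal(methylation_step(st, 0, 0.01, p)$m, 6)
  # step stimulus: sudden drop, then exponential return towards Y0
  tau <- 10; Y0 <- 3
  pp <- pathway_params(tau = tau)
  st <- list(m = 6, F0 = f0_of_y0(Y0, pp))
  dt <- 0.01
  ys <- numeric(0)
  for (i in seq_len(round(8 * tau / dt))) {
    st <- methylation_step(st, 100, dt, pp)
    ys <- c(ys, if (i %% 100 == 0) st$Y else NULL)
  }
  expect_lt(min(ys), 0.1 * Y0)                      # deep initial drop
  y5 <- ys[5 * tau]                                 # sampled at 1 s spacing
  expect_gt(y5, 0.95 * Y0)                          # mostly recovered by 5 tau
  expect_lt(abs(st$Y - Y0) / Y0, 0.01)              # within 1% by 8 tau
  # precise adaptation from arbitrary initial methylation, several (Y0, L)
  for (case in list(c(2, 50), c(3, 500), c(3.5, 200))) {
    Y0 <- case[1]; L <- case[2]
    st <- list(m = as.numeric(adapted_methylation(L, f0_of_y0(Y0, pp), pp)) + 2,
               F0 = f0_of_y0(Y0, pp))
    for (i in seq_len(round(10 * tau / dt))) st <- methylation_step(st, L, dt, pp)
    expect_lt(abs(st$Y - Y0), 1e-3)
  }
})

test_that("swimming through an exponential gradient matches the F-ramp ODE", {
  # evolving m while moving at speed s*v reproduces
  # dF/dt = (F0-F)/tau + s*f(L) to O(dt)
  env <- environment_params(g = 1 / 1000)
  tau <- 10
  pp <- pathway_params(tau = tau)
  dt <- 1e-3
  for (s in c(1, -1)) {
    st <- list(m = as.numeric(adapted_methylation(env$L0, 0, pp)), F0 = 0)
    Fd <- 0; x <- 0
    for (i in seq_len(round(20 / dt))) {
      L <- env$L0 * exp(env$g * x)
      st <- methylation_step(st, L, dt, pp)
      Fd <- Fd + dt * ((0 - Fd) / tau + s * ramp_magnitude(L, env, pp))
      x <- x + s * env$v * dt
    }
    expect_equal(st$F, Fd, tolerance = 1e-3)
  }
})

test_that("quasi-steady free energy under a temporal exponential ramp is ~ tau*N*r", {
  # immobilized-cell ramp L(t) = L0*exp(r*t); in the log-sensing regime the
  # steady deviation is tau*N*r times the local saturation factor
  tau <- 10; r <- 0.005
  pp <- pathway_params(tau = tau)
  st <- list(m = as.numeric(adapted_methylation(200, 0, pp)), F0 = 0)
  dt <- 0.01; t_end <- 8 * tau
  for (i in seq_len(round(t_end / dt))) {
    L <- 200 * exp(r * i * dt)
    st <- methylation_step(st, L, dt, pp)
  }
  L_end <- 200 * exp(r * t_end)
  sat <- L_end * (1 / (pp$Ki_uM + L_end) - 1 / (pp$Ka_uM + L_end))
  expect_equal(st$F, tau * pp$N * r * sat, tolerance = 0.05)
})

test_that("asymmetric methylation kinetics pin the adapted activity and scale with VR", {
  recovery_rate <- function(VR) {
    pa <- pathway_params(variant = "asymmetric", VR = VR)
    Y0 <- 3
    st <- list(m = as.numeric(adapted_methylation(200, f0_of_y0(Y0, pa), pa)),
               F0 = f0_of_y0(Y0, pa), a0 = Y0 / pa$alpha)
    # adapted state is a fixed point
    expect_equal(methylation_step(st, 200, 0.01, pa)$m, st$m, tolerance = 1e-12)
    # small ligand step, then exponential recovery of F
    dts <- 0.01
    st2 <- st
    devs <- c()
    for (i in seq_len(round(40 / dts))) {
      st2 <- methylation_step(st2, 220, dts, pa)
      devs <- c(devs, st2$F - st$F0)
    }
    tt <- seq_along(devs) * dts
    sel <- tt > 2 & devs > 1e-5
    -coef(lm(log(devs[sel]) ~ tt[sel]))[2]
  }
  k1 <- recovery_rate(0.1)
  k4 <- recovery_rate(0.4)
  expect_equal(as.numeric(k4 / k1), 4, tolerance = 0.15)
})

test_that("ramp magnitude matches the spatial derivative and its limits", {
  env <- environment_params(g = 1 / 1000)
  # finite-difference oracle of v * d/dx [ligand term]
  L_of_x <- function(x) env$L0 * exp(env$g * x)
  h <- 1e-4
  fd <- env$v * (chemodrift:::ligand_term(L_of_x(h), p) -
                   chemodrift:::ligand_term(L_of_x(-h), p)) / (2 * h)
  expect_equal(ramp_magnitude(env$L0, env, p), fd, tolerance = 1e-8)
  # log-sensing limit: Ki << L << Ka gives f -> v*N*g
  pwide <- pathway_params(Ki = 1e-5, Ka = 1e5)
  expect_equal(ramp_magnitude(200, env, pwide), env$v * p$N * env$g,
               tolerance = 1e-3)
  # at the study background the saturation factor is below 1
  f200 <- ramp_magnitude(200, env, p)
  expect_true(f200 > 0.8 * env$v * p$N * env$g &&
                f200 < env$v * p$N * env$g)
  # saturation limits
  expect_lt(ramp_magnitude(1e7, env, p), 1e-3 * env$v * p$N * env$g)
  expect_equal(ramp_magnitude(200, environment_params(g = 0), p), 0)
})
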