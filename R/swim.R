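#' Initialize a population of cells
#'
#' All cells start at the origin, adapted to the local ligand concentration
#' `L(0) = L0` (methylation from [adapted_methylation()], so the initial
#' CheY-P is exactly `Y0`), with headings uniform on the sphere, motor mode
#' drawn Bernoulli with tumble probability `TB0`, and the FliM ring at its
#' pre-stimulus size `n0`. Deterministic given the seed.
#'
#' @param n_cells number of cells.
#' @param phen a [phenotype()] object.
#' @param env an [environment_params()] object.
#' @param mp a [motor_params()] object.
#' @param seed integer seed.
#' @return data.frame with one row per cell: `x1, x2, x3`, heading
#'   `u1, u2, u3`, `m`, `Y`, `tumbling`, `n`.
#' @export
init_population <- function(n_cells, phen, env = environment_params(),
                            mp = motor_params(), seed = 1) {
  stopifnot(n_cells >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- adapted_methylation(env$L0, phen$F0, phen$pathway)
  z <- runif(n_cells, -1, 1)
  ph <- runif(n_cells, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  data.frame(x1 = 0, x2 = 0, x3 = 0,
             u1 = r * cos(ph), u2 = r * sin(ph), u3 = z,
             m = as.numeric(m),
             Y = chey_p(free_energy(as.numeric(m), env$L0, phen$pathway),
                        phen$pathway),
             tumbling = runif(n_cells) < phen$TB0,
             n = mp$n0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a swimming population and measure drift
#'
#' Runs the stochastic 3-D run-and-tumble simulation (compiled core) for
#' `n_cells` phenotypically identical cells in the exponential gradient of
#' `env`, and summarizes the population: drift velocity along the gradient
#' axis (per-cell displacement difference over the measurement window,
#' averaged), the operational CheY-P `Y_m` (instantaneous CheY-P averaged
#' over the population and over the window), the mean encountered ligand
#' trace, and the RMS displacement perpendicular to the gradient.
#'
#' @param n_cells number of cells (study scale 10000; desk scale 2000).
#' @param T total simulated time (s); must cover the window.
#' @param phen a [phenotype()] object.
#' @param env an [environment_params()] object.
#' @param mp a [motor_params()] object (`mp$adapt` switches FliM
#'   adaptation on).
#' @param dt integration step (s), `<= 0.01`.
#' @param seed integer master seed; each cell derives its own stream.
#' @param window measurement window `c(t0, t1)` in s.
#' @param sample_dt observable sampling interval (s).
#' @return an object of class `population_result`: list with `summary`
#'   (one-row data.frame: `Y0, tau, g, V_D, SE, Y_m, rms_perp, n_cells`),
#'   `cells` (per-cell `vd`, `perp`, `y_mean`), `traces` (`time`,
#'   `meanY`, `meanL`), `mean_run_length`, and the config echo.
#' @export
run_population <- function(n_cells = 2000, T = 300, phen,
                           env = environment_params(), mp = motor_params(),
                           dt = 0.01, seed = 1, window = c(60, 300),
                           sample_dt = 0.1) {
  stopifnot(n_cells >= 1, dt > 0, dt <= 0.01 + 1e-12,
            T >= window[2], window[1] < window[2])
  p <- phen$pathway
  lam0 <- max(unlist(switching_rates(phen$Y0, mp)))
  if (lam0 * dt > 0.5)
    warning("dt is large relative to the motor switching rates at Y0")
  a0 <- phen$Y0 / p$alpha
  VB <- p$VR * (1 - a0) / a0
  res <- .simulate_population_cpp(
    as.integer(n_cells), T, dt, phen$Y0, phen$tau,
    p$alpha, p$eps0, p$eps1, p$N, p$Ki_uM, p$Ka_uM, p$m_max,
    as.integer(p$variant == "asymmetric"), p$VR, VB,
    mp$omega, mp$eps2, mp$eps3, mp$K,
    as.integer(mp$adapt), mp$k_on, mp$k_off, mp$n1, mp$n2, mp$n0, mp$dn,
    mp$eps3_0, mp$eps3_1,
    env$L0, env$g, env$v, env$Dr,
    window[1], window[2], sample_dt, as.double(seed))
  vd <- (res$x1_w1 - res$x1_w0) / (window[2] - window[1])
  summary <- data.frame(
    Y0 = phen$Y0, tau = phen$tau, g = env$g,
    V_D = mean(vd), SE = sd(vd) / sqrt(n_cells),
    Y_m = res$Y_m, rms_perp = sqrt(mean(res$perp_end^2)),
    n_cells = n_cells)
  structure(list(
    summary = summary,
    cells = data.frame(vd = vd, perp = res$perp_end, y_mean = res$y_cell),
    traces = data.frame(time = res$times, meanY = res$meanY,
                        meanL = res$meanL),
    mean_run_length = res$mean_run_length,
    n_runs = res$n_runs,
    TB0 = res$TB0,
    config = list(phenotype = phen, env = env, motor = mp, dt = dt,
                  T = T, window = window, seed = seed)),
    class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<population_result> %d cells, Y0 = %g uM, tau = %g s, g = %g /um\n",
    s$n_cells, s$Y0, s$tau, s$g))
  cat(sprintf("  V_D = %.3f +/- %.3f um/s; Y_m = %.3f uM; RMS_perp = %.1f um\n",
              s$V_D, s$SE, s$Y_m, s$rms_perp))
  invisible(x)
}

#' Per-cell drift/diffusion scatter and bimodality split
#'
#' Returns the per-cell (drift velocity, perpendicular RMS displacement,
#' window-mean CheY-P) scatter from a [run_population()] result and, when
#' an unstable fixed point is supplied (or found via [fixed_points()]),
#' assigns each cell to the "trapped" or "drifting" mode by thresholding
#' its drift at the unstable point's drift velocity.
#'
#' @param result a [run_population()] result with per-cell series.
#' @param fp optional `fixed_points` table for the same phenotype and
#'   environment; when it contains an unstable root its `V_D` is the
#'   threshold.
#' @return data.frame of per-cell values plus `mode`
#'   (`"drifting"`/`"trapped"`/`NA`); attributes `threshold` and
#'   `trapped_fraction`.
#' @export
bimodality_summary <- function(result, fp = NULL) {
  cells <- result$cells
  thr <- NA_real_
  if (!is.null(fp) && any(!fp$stable))
    thr <- min(fp$V_D[!fp$stable])
  if (!is.na(thr)) {
    cells$mode <- ifelse(cells$vd > thr, "drifting", "trapped")
  } else {
    cells$mode <- NA_character_
  }
  attr(cells, "threshold") <- thr
  attr(cells, "trapped_fraction") <-
    if (!is.na(thr)) mean(cells$mode == "trapped") else NA_real_
  cells
}
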