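#' Experiment configuration
#'
#' Experiments are described by a YAML file with blocks `pathway`,
#' `motor`, `environment`, a `phenotypes` list, and `simulation` controls.
#' Every field has a default (the standard model constants), unknown keys
#' are rejected, and out-of-range values produce structured errors naming
#' the offending field. An empty file therefore yields the full default
#' configuration.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class `experiment_config`: list with elements
#'   `pathway` ([pathway_params()]), `motor` ([motor_params()]),
#'   `environment` ([environment_params()]), `phenotypes` (list of
#'   [phenotype()]), `simulation` (list: `n_cells`, `T`, `dt`, `window`,
#'   `seed`) and `hash` (md5 of the canonical serialization).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

config_defaults <- function() {
  list(
    pathway = list(alpha = 6, eps0 = 6, eps1 = -1, N = 6, Ki = 0.0182,
                   Ka = 3, m_max = 48, variant = "symmetric", VR = 0.1),
    motor = list(omega = 1.3, eps2 = 80, eps3 = 80, K = 3.06,
                 adapt = FALSE, k_on = 0.025, k_off = 0.0063, n1 = 34,
                 n2 = 44, n0 = 36, dn = 4.16, eps3_0 = 80, eps3_1 = 1.96),
    environment = list(L0 = 200, g_inv = 5000, v = 20, Dr = 0.062, d = 3),
    phenotypes = list(list(Y0 = 2.4, tau = 10)),
    simulation = list(n_cells = 10000, T = 300, dt = 0.01,
                      window = c(60, 300), seed = 1)
  )
}

check_keys <- function(block, allowed, name) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in '%s': %s", name,
                 paste(extra, collapse = ", ")))
}

#' @rdname load_config
#' @param raw a nested list in the same shape as the YAML file.
#' @export
build_config <- function(raw = list()) {
  def <- config_defaults()
  check_keys(raw, names(def), "config")
  for (blk in c("pathway", "motor", "environment", "simulation")) {
    if (!is.null(raw[[blk]])) {
      check_keys(raw[[blk]], names(def[[blk]]), blk)
      def[[blk]] <- modifyList(def[[blk]], raw[[blk]])
    }
  }
  if (!is.null(raw$phenotypes)) def$phenotypes <- raw$phenotypes

  pw <- def$pathway
  p <- pathway_params(alpha = pw$alpha, eps0 = pw$eps0, eps1 = pw$eps1,
                      N = pw$N, Ki = pw$Ki, Ka = pw$Ka, m_max = pw$m_max,
                      variant = pw$variant, VR = pw$VR)
  mo <- def$motor
  mp <- motor_params(omega = mo$omega, eps2 = mo$eps2, eps3 = mo$eps3,
                     K = mo$K, adapt = mo$adapt, k_on = mo$k_on,
                     k_off = mo$k_off, n1 = mo$n1, n2 = mo$n2, n0 = mo$n0,
                     dn = mo$dn, eps3_0 = mo$eps3_0, eps3_1 = mo$eps3_1)
  ev <- def$environment
  if (ev[["g_inv"]] <= 0) stop("environment g_inv must be > 0")
  g <- 1 / ev[["g_inv"]]
  env <- environment_params(L0 = ev$L0, g = g, v = ev$v, Dr = ev$Dr,
                            d = ev$d)
  phens <- lapply(def$phenotypes, function(ph) {
    check_keys(ph, c("Y0", "tau"), "phenotypes")
    if (is.null(ph$Y0) || is.null(ph$tau))
      stop("each phenotype needs both 'Y0' and 'tau'")
    if (ph$Y0 <= 0 || ph$Y0 >= p$alpha)
      stop(sprintf("phenotype Y0 = %g uM out of range: must lie in (0, alpha = %g uM)",
                   ph$Y0, p$alpha))
    if (ph$tau <= 0) stop("phenotype tau must be > 0 s")
    phenotype(ph$Y0, ph$tau, p, mp)
  })
  sim <- def$simulation
  if (sim$dt <= 0 || sim$dt > 0.01 + 1e-12)
    stop("simulation dt must lie in (0, 0.01] s")
  cfg <- list(pathway = p, motor = mp, environment = env,
              phenotypes = phens, simulation = sim, raw = def)
  cfg$hash <- config_hash(def)
  class(cfg) <- "experiment_config"
  cfg
}

config_hash <- function(def) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(def[c("pathway", "motor", "environment", "phenotypes",
                         "simulation")], tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname load_config
#' @param cfg an `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg$raw[c("pathway", "motor", "environment",
                             "phenotypes", "simulation")], path)
  invisible(path)
}

#' Canonical study scenarios
#'
#' Named generators for the scenario set used throughout the study:
#' shallow-gradient sweeps of the adapted CheY-P for several adaptation
#' times (`fig2a`), rotational-diffusion (`fig2c`) and motor switching
#' frequency (`fig2d`) sweeps, the steep-gradient behavioral-feedback
#' phenotypes (`fig3`), the bistable "trap" phenotypes (`fig4`), motor
#' adaptation (`fig5`), the trade-off map grids (`fig6`), and asymmetric
#' methylation kinetics (`s1`).
#'
#' @return a named list; each element is a list of configuration pieces
#'   (`env`, `taus`/`phenotypes`/`grids`, sweep values).
#' @export
fixtures <- function() {
  list(
    fig2a = list(g_inv = 5000, taus = c(5, 10, 30),
                 Y0 = seq(1, 4, by = 0.2)),
    fig2c = list(g_inv = 5000, tau = 10, Y0 = seq(1, 4, by = 0.2),
                 Dr = c(0.031, 0.062, 0.124)),
    fig2d = list(g_inv = 5000, tau = 10, Y0 = seq(1, 4, by = 0.2),
                 omega = c(0.65, 1.3, 2.6)),
    fig3 = list(g_inv = 1000,
                phenotypes = list(c(Y0 = 2.4, tau = 10),
                                  c(Y0 = 2.4, tau = 30),
                                  c(Y0 = 3.0, tau = 10))),
    fig4 = list(g_inv = 1000,
                fixed_point_cases = list(c(Y0 = 2.7, tau = 5),
                                         c(Y0 = 3.5, tau = 30)),
                sim_phenotypes = list(c(Y0 = 2.6, tau = 10),
                                      c(Y0 = 3.0, tau = 30))),
    fig5 = list(g_inv = 1000, trap = c(Y0 = 3.5, tau = 30),
                motor_adapt = TRUE),
    fig6 = list(g_inv = c(1000, 2000, 5000), tau_range = c(1, 30),
                TB0_range = c(0.01, 0.4), motor_adapt = TRUE),
    s1 = list(g_inv = 5000, tau = 10, Y0 = seq(1.8, 3.4, by = 0.4),
              VR = c(0.1, 0.2, 0.4))
  )
}

#' Execute a canonical scenario and write its tables
#'
#' Runs one of the [fixtures()] scenarios at full (10000 cells) or desk
#' (2000 cells) scale and writes the resulting summary tables as CSV files
#' with unit-bearing headers, plus a small run manifest (seed, scale,
#' runtime). Identical seeds give identical outputs.
#'
#' @param name scenario name, one of `names(fixtures())`.
#' @param out_dir output directory (created if missing).
#' @param scale `"desk"` (2000 cells) or `"full"` (10000 cells).
#' @param seed master seed.
#' @param n_cells optional explicit override of the population size.
#' @param T simulated duration (s).
#' @return (invisibly) the paths of the files written.
#' @export
run_figure <- function(name, out_dir, scale = c("desk", "full"), seed = 1,
                       n_cells = NULL, T = 300) {
  scale <- match.arg(scale)
  fx <- fixtures()
  if (!name %in% names(fx)) stop("unknown fixture name: ", name)
  if (is.null(n_cells)) n_cells <- if (scale == "desk") 2000 else 10000
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- fx[[name]]
  t0 <- Sys.time()
  p <- pathway_params()
  mp <- motor_params()
  files <- character(0)
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  win <- c(60, T)

  if (name %in% c("fig2a", "fig2c", "fig2d", "s1")) {
    env0 <- environment_params(g = 1 / sc$g_inv)
    sweep <- switch(name,
      fig2a = data.frame(tau = rep(sc$taus, each = length(sc$Y0)),
                         Y0 = rep(sc$Y0, length(sc$taus)),
                         Dr = env0$Dr, omega = mp$omega, VR = NA),
      fig2c = data.frame(tau = sc$tau, Y0 = rep(sc$Y0, length(sc$Dr)),
                         Dr = rep(sc$Dr, each = length(sc$Y0)),
                         omega = mp$omega, VR = NA),
      fig2d = data.frame(tau = sc$tau, Y0 = rep(sc$Y0, length(sc$omega)),
                         Dr = env0$Dr,
                         omega = rep(sc$omega, each = length(sc$Y0)),
                         VR = NA),
      s1 = data.frame(tau = sc$tau, Y0 = rep(sc$Y0, length(sc$VR)),
                      Dr = env0$Dr, omega = mp$omega,
                      VR = rep(sc$VR, each = length(sc$Y0))))
    rows <- lapply(seq_len(nrow(sweep)), function(i) {
      r <- sweep[i, ]
      env <- environment_params(g = env0$g, Dr = r$Dr)
      mpi <- motor_params(omega = r$omega)
      pi <- if (name == "s1") pathway_params(variant = "asymmetric",
                                             VR = r$VR) else p
      phen <- phenotype(r$Y0, r$tau, pi, mpi)
      sim <- run_population(n_cells, T, phen, env, mpi, seed = seed,
                            window = win)$summary
      ana <- drift_linearized(operating_point(r$Y0, pi, env, mpi), r$tau,
                              env, p = pi)
      cbind(r, sim[c("V_D", "SE", "Y_m", "rms_perp")], V_D_analytic = ana)
    })
    tab <- do.call(rbind, rows)
    names(tab) <- c("tau_s", "Y0_uM", "Dr_rad2_per_s", "omega_per_s", "VR_per_s",
                    "V_D_um_per_s", "SE_um_per_s", "Y_m_uM", "rms_perp_um",
                    "V_D_analytic_um_per_s")
    emit(tab, paste0(name, "_drift.csv"))
  } else if (name == "fig3") {
    env <- environment_params(g = 1 / sc$g_inv)
    for (ph in sc$phenotypes) {
      phen <- phenotype(ph[["Y0"]], ph[["tau"]], p, mp)
      res <- run_population(n_cells, T, phen, env, mp, seed = seed,
                            window = win)
      tr <- res$traces
      names(tr) <- c("time_s", "mean_Y_uM", "mean_L_uM")
      emit(tr, sprintf("fig3_trace_Y0_%g_tau_%g.csv", ph[["Y0"]],
                       ph[["tau"]]))
      emit(res$summary, sprintf("fig3_summary_Y0_%g_tau_%g.csv",
                                ph[["Y0"]], ph[["tau"]]))
    }
  } else if (name == "fig4") {
    env <- environment_params(g = 1 / sc$g_inv)
    fp_rows <- lapply(sc$fixed_point_cases, function(ph) {
      phen <- phenotype(ph[["Y0"]], ph[["tau"]], p, mp)
      fp <- fixed_points(phen, env, mp)
      cbind(Y0_uM = ph[["Y0"]], tau_s = ph[["tau"]],
            Y_m_uM = fp$Y_m, V_D_um_per_s = fp$V_D, stable = fp$stable)
    })
    emit(as.data.frame(do.call(rbind, fp_rows)), "fig4_fixed_points.csv")
    for (ph in sc$sim_phenotypes) {
      phen <- phenotype(ph[["Y0"]], ph[["tau"]], p, mp)
      res <- run_population(n_cells, T, phen, env, mp, seed = seed,
                            window = win)
      cells <- res$cells
      names(cells) <- c("vd_um_per_s", "perp_um", "y_mean_uM")
      emit(cells, sprintf("fig4_cells_Y0_%g_tau_%g.csv", ph[["Y0"]],
                          ph[["tau"]]))
    }
  } else if (name == "fig5") {
    mpa <- motor_params(adapt = TRUE)
    env <- environment_params(g = 1 / sc$g_inv)
    yg <- seq(0.5, 5.5, by = 0.05)
    curve <- adapted_cw_curve(yg, mpa)
    names(curve) <- c("Y_uM", "CW", "n_FliM", "eps3", "pinned")
    emit(curve, "fig5_adapted_cw_curve.csv")
    phen <- phenotype(sc$trap[["Y0"]], sc$trap[["tau"]], p, mpa)
    fp <- fixed_points(phen, env, mpa, motor_adapt = TRUE)
    emit(data.frame(Y_m_uM = fp$Y_m, V_D_um_per_s = fp$V_D,
                    stable = fp$stable), "fig5_fixed_points.csv")
  } else if (name == "fig6") {
    mpa <- motor_params(adapt = TRUE)
    taus <- exp(seq(log(sc$tau_range[1]), log(sc$tau_range[2]),
                    length.out = 12))
    opt_rows <- lapply(sc$g_inv, function(gi) {
      env <- environment_params(g = 1 / gi)
      do.call(rbind, lapply(taus, function(tv) {
        o <- optimal_Y0(tv, env, mpa, p, motor_adapt = TRUE)
        data.frame(g_inv_um = gi, tau_s = tv, Y0_opt_uM = o$Y0_opt,
                   Y_m_uM = o$Y_m, V_D_um_per_s = o$V_D,
                   bifurcated = o$bifurcated)
      }))
    })
    emit(do.call(rbind, opt_rows), "fig6_optimal_Y0.csv")
    pm <- phenotype_map(gradients = 1 / sc$g_inv, p = p, mp = mpa)
    mm <- pm$maximin
    emit(data.frame(tau_s = mm$tau, TB0 = mm$TB0, Y0_uM = mm$Y0,
                    worst_case_relative = mm$relative),
         "fig6_maximin.csv")
  }

  manifest <- data.frame(fixture = name, scale = scale, n_cells = n_cells,
                         T_s = T, seed = seed,
                         runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs")),
                         version = as.character(utils::packageVersion("chemodrift")))
  emit(manifest, paste0(name, "_manifest.csv"))
  invisible(files)
}

#' Compare an analytic sweep against a simulated sweep
#'
#' Joins two drift tables on their shared phenotype grid and reports
#' per-point relative error, the location of each table's peak, and a
#' pass/fail against a stated tolerance at the peak.
#'
#' @param analytic_table,sim_table data.frames with columns `Y0`, `V_D`
#'   (and optionally `tau`); grids must match.
#' @param tol relative tolerance at the simulated peak.
#' @return list with the joined table, `max_rel_err_at_peak`,
#'   `peak_shift`, and `pass`.
#' @export
compare_runs <- function(analytic_table, sim_table, tol = 0.15) {
  key <- intersect(c("tau", "Y0"), intersect(names(analytic_table),
                                             names(sim_table)))
  j <- merge(analytic_table, sim_table, by = key,
             suffixes = c("_analytic", "_sim"))
  if (!nrow(j)) stop("phenotype grids do not overlap")
  if (nrow(j) < max(nrow(analytic_table), nrow(sim_table)))
    warning("phenotype grids only partially overlap")
  j$rel_err <- (j$V_D_analytic - j$V_D_sim) / pmax(abs(j$V_D_sim), 1e-12)
  peak_sim <- j$Y0[which.max(j$V_D_sim)]
  peak_ana <- j$Y0[which.max(j$V_D_analytic)]
  near_peak <- j$V_D_sim >= 0.8 * max(j$V_D_sim)
  err_peak <- max(abs(j$rel_err[near_peak]))
  list(table = j, max_rel_err_at_peak = err_peak,
       peak_shift = peak_ana - peak_sim, pass = err_peak <= tol)
}
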