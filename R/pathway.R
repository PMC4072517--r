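#' Receptor-pathway parameters
#'
#' Constants of the coarse-grained sensory module: a cooperative (MWC)
#' cluster of Tar receptors sensing methyl-aspartate, whose kinase activity
#' is summarized by the free-energy difference `F` between inactive and
#' active conformations, and whose output is the CheY-P concentration
#' `Y = alpha / (1 + exp(F))`.
#'
#' @param alpha gain of the phosphorylation cascade (µM); maximum CheY-P.
#' @param eps0 free-energy offset (dimensionless).
#' @param eps1 per-methylation free-energy increment (dimensionless,
#'   negative: methylation activates the cluster).
#' @param N receptor cooperativity gain (number of receptor dimers per
#'   signalling unit).
#' @param Ki,Ka ligand dissociation constants of the inactive and active
#'   conformations (mM; converted to µM internally).
#' @param m_max total methylation sites per cooperative unit.
#' @param tau methylation adaptation time (s).
#' @param variant `"symmetric"` for the spring-like relaxation of `F`
#'   towards `F0`, or `"asymmetric"` for activity-dependent first-order
#'   methylation/demethylation kinetics.
#' @param VR methylation rate (s^-1), asymmetric variant only.
#'
#' @return an object of class `pathway_params`.
#' @export
#' @examples
#' p <- pathway_params()
#' free_energy(6, 0, p)  # adapted state at zero ligand when Y0 = alpha/2
pathway_params <- function(alpha = 6, eps0 = 6, eps1 = -1, N = 6,
                           Ki = 0.0182, Ka = 3, m_max = 48,
                           tau = 10, variant = c("symmetric", "asymmetric"),
                           VR = 0.1) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, N >= 1, Ki > 0, Ki < Ka, m_max > 0, tau > 0,
            eps1 != 0, VR > 0)
  structure(list(alpha = alpha, eps0 = eps0, eps1 = eps1, N = N,
                 Ki_uM = Ki * 1000, Ka_uM = Ka * 1000, m_max = m_max,
                 tau = tau, variant = variant, VR = VR),
            class = "pathway_params")
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("<pathway_params>",
      sprintf("alpha = %g uM, eps0 = %g, eps1 = %g, N = %g", x$alpha,
              x$eps0, x$eps1, x$N),
      sprintf("Ki = %g uM, Ka = %g uM, m_max = %g", x$Ki_uM, x$Ka_uM,
              x$m_max),
      sprintf("tau = %g s, variant = %s", x$tau, x$variant), sep = "\n")
  invisible(x)
}

# ligand contribution to the free-energy difference (log-sensing term)
ligand_term <- function(L, p) {
  p$N * log((1 + L / p$Ki_uM) / (1 + L / p$Ka_uM))
}

#' Receptor-cluster free-energy difference
#'
#' `F(m, L) = eps0 + eps1 * m + N * log((1 + L/Ki) / (1 + L/Ka))`, the
#' free-energy difference between the inactive and active receptor
#' conformations. Increasing attractant raises `F` (lowers kinase
#' activity); methylation lowers it (slope `eps1 < 0`).
#'
#' @param m methylation level, in `[0, m_max]` (may be fractional).
#' @param L ligand concentration (µM), `>= 0`.
#' @param p a [pathway_params()] object.
#' @return free-energy difference (dimensionless), vectorized over `m`/`L`.
#' @export
free_energy <- function(m, L, p = pathway_params()) {
  if (any(L < 0)) stop("ligand concentration L must be >= 0")
  if (any(m < 0 | m > p$m_max))
    stop(sprintf("methylation level must lie in [0, %g]", p$m_max))
  p$eps0 + p$eps1 * m + ligand_term(L, p)
}

#' CheY-P concentration from free energy, and its inverse
#'
#' `chey_p()` maps the free-energy difference to the CheY-P concentration
#' `Y = alpha / (1 + exp(F))`; `f0_of_y0()` is the inverse
#' `F = log(alpha/Y - 1)`, used to turn an adapted concentration `Y0` into
#' the adapted free energy `F0`.
#'
#' @param F free-energy difference (dimensionless).
#' @param Y0 CheY-P concentration (µM), strictly inside `(0, alpha)`.
#' @inheritParams free_energy
#' @return `chey_p()`: CheY-P in µM; `f0_of_y0()`: free energy.
#' @export
chey_p <- function(F, p = pathway_params()) {
  p$alpha / (1 + exp(F))
}

#' @rdname chey_p
#' @export
f0_of_y0 <- function(Y0, p = pathway_params()) {
  if (any(Y0 <= 0 | Y0 >= p$alpha))
    stop(sprintf("Y0 must lie strictly between 0 and alpha = %g uM",
                 p$alpha))
  log(p$alpha / Y0 - 1)
}

#' Methylation level of a cell adapted to a ligand background
#'
#' Solves `free_energy(m, L) = F0` for `m`. The solution is closed-form
#' (linear in `m`); it is clamped into `[0, m_max]` and flagged when the
#' required methylation exceeds the available range (precise adaptation
#' then fails).
#'
#' @param L background ligand concentration (µM).
#' @param F0 adapted free-energy difference.
#' @inheritParams free_energy
#' @return numeric vector of methylation levels with attribute `clamped`
#'   (logical vector).
#' @export
adapted_methylation <- function(L, F0, p = pathway_params()) {
  if (any(L < 0)) stop("ligand concentration L must be >= 0")
  m <- (F0 - p$eps0 - ligand_term(L, p)) / p$eps1
  clamped <- m < 0 | m > p$m_max
  m <- pmin(pmax(m, 0), p$m_max)
  attr(m, "clamped") <- clamped
  m
}

#' Advance the methylation state by one Euler step
#'
#' Symmetric variant: `dm/dt = (F0 - F) / (tau * eps1)` so that the
#' methylation contribution to `dF/dt` is `(F0 - F)/tau` — at constant
#' ligand, `F` relaxes exponentially to `F0` with time constant `tau`
#' (precise adaptation). Asymmetric variant: `dm/dt = VR*(1 - a) - VB*a`
#' with activity `a = Y/alpha` and `VB = VR*(1 - a0)/a0` pinned so the
#' adapted activity `a0` is the zero of `dm/dt`.
#'
#' @param state list with at least `m` (methylation) and `F0` (adapted free
#'   energy); for the asymmetric variant also `a0` (adapted activity).
#' @param L local ligand concentration (µM).
#' @param dt time step (s), `dt << tau`.
#' @inheritParams free_energy
#' @return the updated state: `m`, `F` (free energy after the step), and
#'   `Y` (CheY-P after the step).
#' @export
methylation_step <- function(state, L, dt, p = pathway_params()) {
  stopifnot(dt > 0)
  F_now <- free_energy(state$m, L, p)
  if (p$variant == "symmetric") {
    dm <- (state$F0 - F_now) / (p$tau * p$eps1)
  } else {
    a <- chey_p(F_now, p) / p$alpha
    a0 <- state$a0
    if (is.null(a0)) stop("asymmetric variant needs the adapted activity a0")
    if (a0 <= 0 || a0 >= 1) stop("adapted activity a0 must lie in (0, 1)")
    VB <- p$VR * (1 - a0) / a0
    dm <- p$VR * (1 - a) - VB * a
  }
  m_new <- min(max(state$m + dt * dm, 0), p$m_max)
  F_new <- free_energy(m_new, L, p)
  state$m <- m_new
  state$F <- F_new
  state$Y <- chey_p(F_new, p)
  state
}

#' Rate of free-energy change imposed by swimming through a gradient
#'
#' For a cell swimming at speed `v` through `L(x) = L0*exp(g*x)`, the
#' ligand term of the free energy changes at rate
#' `f(x) = v * N * d/dx log((1 + L/Ki)/(1 + L/Ka))`. In the log-sensing
#' regime `Ki << L << Ka` this saturates to the constant `f = v*N*g` — the
#' constant "force" exploited by the exponential-gradient design.
#'
#' @param L local ligand concentration (µM).
#' @param env an [environment_params()] object (uses `v` and `g`).
#' @inheritParams free_energy
#' @return `f` in s^-1, vectorized over `L`.
#' @export
ramp_magnitude <- function(L, env, p = pathway_params()) {
  # d/dx ln((1+L/Ki)/(1+L/Ka)) with dL/dx = g*L
  env$v * p$N * env$g * L * (1 / (p$Ki_uM + L) - 1 / (p$Ka_uM + L))
}
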