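---
title: "Models and methods behind chemodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemodrift)
```

chemodrift studies how a single *E. coli* cell's signalling phenotype —
its adapted CheY-P concentration $Y_0$ and receptor adaptation time
$\tau$ — determines its chemotactic drift velocity $V_D$ in exponential
attractant gradients $L(x) = L_0 e^{gx}$, and how the cell's own drift
feeds back on the signal it senses. This vignette documents the models,
the numerical choices, and the design decisions taken where the design
was genuinely open.

## The sensory module

Receptor-kinase complexes are modelled as a cooperative two-state (MWC)
cluster. Kinase activity is summarized by the free-energy difference
between inactive and active conformations,

$$F(m, L) = \epsilon_0 + \epsilon_1 m +
  N \ln\!\frac{1 + L/K_i}{1 + L/K_a},$$

with methylation level $m$ and ligand concentration $L$. The output of
the pathway, the CheY-P concentration, is
$Y = \alpha / (1 + e^{F})$, so $F = \ln(\alpha/Y - 1)$. Defaults
(`pathway_params()`): $\alpha = 6$ µM, $\epsilon_0 = 6$,
$\epsilon_1 = -1$, $N = 6$, $K_i = 18.2$ µM, $K_a = 3$ mM (Tar receptors
sensing methyl-aspartate), $m_{\max} = 48$ sites per cooperative unit.
Concentrations are µM internally everywhere.

Methylation implements integral feedback. The default ("symmetric")
kinetics are the minimal law whose free-energy footprint is spring-like,

$$\frac{dm}{dt} = \frac{F_0 - F}{\tau\,\epsilon_1}
  \quad\Longrightarrow\quad
  \frac{dF}{dt} = \frac{F_0 - F}{\tau} + s\,f,$$

where $F_0 = \ln(\alpha/Y_0 - 1)$ is the adapted free energy, $s = \pm 1$
or $0$ is the direction of motion relative to the gradient, and

$$f(L) = v N g\, L\left(\frac{1}{K_i + L} - \frac{1}{K_a + L}\right)$$

is the rate at which swimming changes the ligand term
(`ramp_magnitude()`). In the log-sensing regime $K_i \ll L \ll K_a$,
$f \to vNg$, a constant "force" — the reason exponential gradients admit
a steady-state drift velocity. At the study background $L_0 = 200$ µM the
saturation factor is $0.854$, which matters when comparing theory with
simulation (below). An activity-dependent ("asymmetric") variant
$dm/dt = V_R(1-a) - V_B\,a$ with $a = Y/\alpha$ and $V_B$ pinned so the
adapted activity is the zero of $dm/dt$ is available for sensitivity
analysis; only $V_R$ values are calibrated, so pinning $V_B$ by the set
point is our convention. $m$ is continuous and deterministic — the
model's stochasticity lives entirely in the motor.

## The motor module

The flagellar motor is a bistable two-state system (CCW = run, CW =
tumble) with free-energy difference
$\Delta G(Y) = \epsilon_2/2 - \epsilon_3\, Y/(Y + K)$ and symmetric
Arrhenius switching rates
$\lambda_R = \omega e^{-\Delta G/2}$, $\lambda_T = \omega e^{+\Delta G/2}$,
so $\lambda_R \lambda_T = \omega^2$ exactly and the stationary CW bias is
$1/(1 + e^{\Delta G})$. With $\epsilon_2 = \epsilon_3 = 80$,
$K = 3.06$ µM and $\omega = 1.3$ s$^{-1}$, the response half-max sits at
$K$ with an effective Hill coefficient of 20.0 — the functional form is a
reconstruction pinned by exactly these calibration facts, and the Hill
coefficient is one of the package's acceptance checks. A single motor is
simulated, so motor CW bias and cell tumble bias coincide.

### FliM-ring adaptation

The slow (~minutes) remodelling of the motor's FliM ring is a continuous
binding/unbinding process on $n \in [n_1, n_2]$:

$$\frac{dn}{dt} = k_{\rm off}(1 - CW)\frac{n_2 - n}{(n_2 - n) + \Delta n}
  - k_{\rm on}\, CW\, \frac{n - n_1}{(n - n_1) + \Delta n},
  \qquad \epsilon_3(n) = \epsilon_{3,0} + \epsilon_{3,1}(n - n_0).$$

CCW rotation recruits FliM (rate constant $k_{\rm off} = 0.0063$
s$^{-1}$, the binding-side constant in the source calibration), CW
rotation releases it ($k_{\rm on} = 0.025$ s$^{-1}$); because
$\epsilon_3$ grows with $n$, this is a stable negative feedback that
adapts the motor towards $CW = k_{\rm off}/(k_{\rm on} + k_{\rm off})
\approx 0.2$. The assignment of the two rate constants was the one
genuinely open design choice in this module: the reverse assignment
either adapts the motor to $CW \approx 0.8$ or turns the feedback
positive (a switch-like, hysteretic response). The adopted law is the
only one of the three candidates that simultaneously (i) adapts to
$CW \approx 0.2$, (ii) yields an adapted response curve with effective
Hill coefficient $\approx 9.6$ and half-max $\approx 3.2$ µM — the
shallow single-motor curve measured under slow CheY-P modulation — and
(iii) collapses the bistable "trap" (below) to a unique stable state at
$Y_m \approx 1.6$ µM. `adapted_cw_curve()` exposes the quasi-steady joint
root of $dn/dt = 0$ and the motor response; the simulator integrates $n$
explicitly per cell.

## The swimming simulator

`run_population()` integrates, per cell and per time step $dt$ (default
0.01 s): the methylation Euler step at the local ligand concentration;
CheY-P and the switching rates; a Bernoulli mode switch with
$p = 1 - e^{-\lambda dt}$; motion (runs advance the position at
$v = 20$ µm/s and diffuse the heading; tumbles hold the cell in place and
redraw the heading uniformly on exit — directional persistence is
deliberately excluded); and, optionally, the FliM ring. Rotational
diffusion adds two independent Gaussian angular increments of variance
$2 D_r dt$ ($D_r = 0.062$ rad$^2$/s) in the plane perpendicular to the
heading, which realizes the 3-D heading autocorrelation $e^{-2 D_r t}$;
the pure-run RMS displacement matches the closed-form prediction to
within 0.3%. Each cell owns an independent `mt19937_64` stream seeded
from (master seed, cell index), so results are reproducible and the
first $k$ cells of a larger population reproduce a smaller one.

Drift velocity is the population mean of the per-cell displacement
difference along the gradient axis over the measurement window (default
60–300 s of a 300 s run); the operational CheY-P $Y_m$ is the
instantaneous CheY-P averaged over cells and over the window. The study
scale is 10,000 cells; the desk scale used by the tests and the
acceptance script is 2,000 cells (drift SE ≈ 0.04 µm/s), with smaller
populations in property tests where only signs or ratios matter. A
dt-halving control keeps the discretization error of the drift below 2%.

## The drift-velocity theory

The analytic layer reduces 3-D run-and-tumble motion to a 1-D two-state
process: runs up/down the gradient terminated by tumbling
($\lambda_R$) or by rotational reorientation (jump rate $(d-1)D_r$), so
the expected run duration along a direction is
$\tau_R = [(d-1)D_r + \lambda_R]^{-1}$ and the drift is

$$V_D = \frac{v}{d}\,
  \frac{\langle t_{up}\rangle - \langle t_{down}\rangle}
       {\langle t_{up}\rangle + \langle t_{down}\rangle + 2\langle t_T\rangle}.$$

`expected_run_duration()` evaluates the exact survival integral
$\int_0^\infty \exp(-\int_0^t \lambda'_R(F(t'))\,dt')\,dt$ with $F(t)$
the closed-form relaxation under a constant ramp $s f$ (trapezoidal
quadrature with step-halving to $10^{-5}$ relative). Linearizing around
the operating point gives (`drift_linearized()`)

$$V_D = \frac{v}{d}\, f\, G\, \tau_R^2\,
  \frac{\tau\,\tau_R}{\tau + \tau_R}\, \frac{1}{\tau_R + \tau_T},$$

with $G = -d\lambda_R/dF$ the tumbling-rate sensitivity (chain rule
through $dY/dF = Y(Y/\alpha - 1)$) and $\tau_T = 1/\lambda_T$. The $1/d$
prefactor is the dimensional rescaling of the 1-D theory; with $d = 3$
this expression reproduces the calibration fixed-point coordinates (the
weak-feedback and bistable reference cases checked by the acceptance
suite) to 0.01 µM, which is how the reconstruction was validated. Drift is maximal
where the *contrast* between run durations up and down the gradient is
maximal — at the foot of the CW response, near $Y \approx 2.4$ µM — not
where the CW bias is steepest.

Two conventions deserve note when comparing theory with simulation:

* The theory defaults to the idealized $f = vNg$, matching the printed
  fixed-point values. The simulated environment has finite $K_i$, so
  concordance checks feed the exact local $f(L_0) = 0.854\,vNg$ into the
  linearized curve; with it, simulation and theory agree at the shallow
  curve peaks to 3% ($\tau=5$ s), 7% ($\tau=10$ s) and 10.5%
  ($\tau=30$ s).
* The residual $\tau$-dependent gap is the renewal approximation: the
  theory restarts every run at the operating free energy, whereas real
  (and simulated) cells carry $F$ across direction changes. A 1-D
  jump-process Monte Carlo with full memory drifts substantially slower
  than the renewal theory at $\tau = 30$ s; the 3-D simulation sits in
  between.

## Behavioral feedback, fixed points, and the trap

A population drifting at $V_D$ rides an average exponential ramp, so its
quasi-steady ("operational") free energy obeys
$F_m = F_0 + \tau N g V_D$ (`feedback_line()`): the operational CheY-P
$Y_m$ lies below $Y_0$ whenever the cell drifts. Steady states are
intersections of this line with the drift curve evaluated *at* $Y_m$
(`fixed_points()`): residual sign changes on a 0.0025 µM grid, refined by
bisection to $10^{-9}$; stability follows the mean-field dynamics
$dF/dt = (F_0 - F)/\tau + N g V_D(Y(F))$ and is cross-checked in the
tests by forward integration. Weak feedback ($\tau N g$ small) gives one
stable point; strong feedback can give three — a fast-drifting state, an
unstable separator, and a near-zero-drift "trap" just below $Y_0$.
Because populations are initialized adapted ($Y_m = Y_0$), the mean-field
reaches the *largest-$Y_m$* stable root; individual stochastic cells
escape the trap and re-enter it, producing the skewed per-cell drift
distributions quantified by `bimodality_summary()`. With FliM adaptation
the drift curve is re-evaluated at the quasi-steady
$\epsilon_3(Y_m)$ (motor remodelling is slow compared with runs, so it is
frozen within the linearization), which removes the trap for the
canonical trap phenotype ($Y_0 = 3.5$ µM, $\tau = 30$ s, $g^{-1} = 1000$
µm) and leaves a unique stable state at $Y_m \approx 1.6$ µM.

The steep-gradient optimum of the *simulated* steady-state drift
(≈2.6 µM at $\tau = 10$ s, $g^{-1} = 1000$ µm) sits below the analytic
fixed-point optimum (≈3.0 µM): near the bifurcation the average includes
transiently trapped cells and the linearization overestimates the fast
branch. The package therefore treats the simulation as the authority for
that quantity and the analytic route as the fast approximation.

## Phenotype maps and the generalist

`phenotype_map()` grids phenotypes by $(\tau, TB_0)$ — adaptation time
and adapted tumble bias — converts $TB_0$ to $Y_0$ by inverting the same
(FliM-adapted) motor response used for the dynamics, and computes the
reachable steady-state drift for each gradient
($g^{-1} \in \{1000, 2000, 5000\}$ µm). Each gradient's surface is
normalized by that gradient's maximal *accessible* drift — the
reachable-state optimum over unconstrained $Y_0 \in [1, 4.5]$ µM, which
may lie outside the mapped $TB_0$ range; the bifurcation bounds it from
above. The within-grid maximum of a relative surface can therefore be
below 1. The maximin (generalist) phenotype maximizes the worst-case
relative performance across gradients; on the default 50×50 log-spaced
grid it reaches ≈64% at $\tau \approx 6.5$ s, $TB_0 \approx 0.049$, on a
ridge flat enough that $(\tau = 7.5\ \text{s}, TB_0 = 0.044)$ achieves
≈61%. Steep gradients favour short $\tau$ and high $TB_0$; shallow
gradients the reverse — no single phenotype is optimal everywhere.

```{r map-example, eval = FALSE}
pm <- phenotype_map()
pm$maximin
```

## Degenerate inputs and numerical guards

* `f0_of_y0()` rejects $Y_0 \notin (0, \alpha)$; methylation and the
  FliM ring are clamped to their physical ranges, with a `clamped` flag
  where precise adaptation is thereby lost.
* `expected_run_duration()` rejects the non-convergent case
  $\lambda_R \to 0$ with $D_r = 0$.
* Switching uses per-step Bernoulli probabilities $1 - e^{-\lambda dt}$,
  which remain well-behaved when $\lambda dt$ is large (the step then
  switches almost surely); `run_population()` warns when the rates at
  $Y_0$ are large relative to `dt`.
* Fixed-point tangencies (exactly at the bifurcation) appear as two
  near-coincident roots at the grid resolution; the scan grid (0.0025 µM)
  is chosen an order of magnitude below every tolerance used downstream.

## What the generator does and does not emulate

The synthetic populations emulate: Poissonian motor switching,
rotational diffusion, precise-adaptation pathway dynamics, behavioral
feedback, and slow motor remodelling — the ingredients of the model
family studied here. They do not emulate: multiple flagellar motors and
bundle mechanics, directional persistence of tumbles, receptor-cluster
or phosphorylation noise, cell-to-cell parameter variability within one
population, ligand consumption, or hydrodynamics. Passing tests
therefore validate the implementation of this model class and its
internal consistency, not the behaviour of real cells beyond what the
model family captures.
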