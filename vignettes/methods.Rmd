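---
title: "Emulating a 1D pulmonary pulse-wave model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a 1D pulmonary pulse-wave model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pwemu` studies how well two families of statistical surrogates — Gaussian
processes (GPs) and polynomial chaos expansions (PCEs) — emulate a
one-dimensional haemodynamics simulator of the pulmonary arterial
circulation, in forward prediction and in inverse parameter estimation. The
package contains the simulator itself (the data generator for the whole
study), Sobol-sequence experimental designs, a principal-component reduction
of the waveform output, four emulator variants (GP.time, GP.PCA, PCE.time,
PCE.PCA), PCE-based Sobol sensitivity indices, and an orchestration layer
that selects hyperparameters on validation data and scores emulators on test
data. The package's functions, scripts and this vignette are its interface;
there is no separate command-line binary.

# The haemodynamics model

Blood flow in each vessel is described by the cross-section-averaged mass and
momentum balance for area $A(x,t)$ (cm²), flow $q(x,t)$ (ml/s) and pressure
$p(x,t)$ (mmHg):

$$\frac{\partial A}{\partial t} + \frac{\partial q}{\partial x} = 0, \qquad
  \frac{\partial q}{\partial t}
  + \frac{\gamma+2}{\gamma+1}\frac{\partial}{\partial x}\frac{q^2}{A}
  + \frac{A}{\rho}\frac{\partial p}{\partial x}
  = -\frac{2\pi\mu(\gamma+2)}{\rho}\frac{q}{A},$$

with blood density $\rho = 1.055$ g/ml, viscosity $\mu = 0.049$, and a blunt
power-law velocity profile with exponent $\gamma = 9$. The viscosity constant
is printed in kinematic units (cm²/s) in the murine literature while the
momentum equation divides it by $\rho$; the solver implements the equation
literally and `fluid_properties(mu_is_kinematic = TRUE)` switches to reading
$\mu$ as the kinematic viscosity directly. The difference is under 5% of the
friction term and invisible at waveform scale.

The tube law closes the system. The default is
$p = p_\mathrm{ref} + \frac{Eh}{r_0}\left(\sqrt{A/A_0} - 1\right)$, whose
characteristic structure gives closed-form Riemann invariants
$u \pm 4c$; a strictly-linear-in-$A$ alternative
($p = p_\mathrm{ref} + \frac{Eh}{r_0}(A/A_0 - 1)$, invariants $u \pm 2c$) is
available via `simulation_config(law = "linear")`. Which of the two
reproduces any particular published waveform is deliberately left to
configuration. Wall stiffness follows
$Eh/r_0 = k_1 e^{-k_2 r_0} + k_3$, increasing sharply for small radii;
nominal values $k_1 = 10^4$ mmHg, $k_2 = 30$ cm⁻¹, $k_3 = 2\times10^4$ mmHg.

Two outflow models close the terminal vessels:

* **Windkessel (WK)** — an RCR circuit per terminal: proximal resistance in
  series with parallel distal resistance and compliance. Per-terminal
  nominals distribute a total resistance (130 mmHg·s/ml) and compliance
  (10⁻³ ml/mmHg) across terminals in proportion to $r_0^3$ (Murray-type flow
  split), with 10% of each terminal's resistance placed proximally. Global
  scale factors $r_p$, $r_d$, $c_T$ multiply every terminal's elements; they
  are three of the emulated biophysical parameters.
* **Structured tree (ST)** — a self-similar asymmetric binary tree per
  terminal, with daughter radius factors $\alpha$ (large) and $\beta$
  (small), length-to-radius ratio $\ell_{rr}$, a minimum radius
  $r_\mathrm{min}$ below which no daughter is spawned, and its own
  small-artery stiffness law. The root input impedance is computed per cycle
  harmonic from the linearized Womersley-profile wave solution per segment
  (compliance from the stiffness law at the segment radius), leaves closed
  with zero distal impedance — the standard convention; a terminal
  resistance could be substituted but zero is the default. Impedances
  combine by series transfer along segments and parallel admittance addition
  at bifurcations, memoized over the $\alpha^i\beta^j$ radius lattice. The
  solver applies the resulting impedance as a periodic time-domain
  convolution kernel (32 samples/cycle, 16 harmonics — the Nyquist limit).

# Numerics

The solver is an explicit Richtmyer two-step Lax–Wendroff scheme on
node-centred grids (default 24 cells/vessel, CFL 0.5); because each vessel
has constant stiffness and reference area, the pressure-gradient term is
integrated in conservative form. Boundaries are closed characteristically:
prescribed inflow at the root, an affine pressure–flow relation at terminals
(trapezoidal update of the WK capacitor state; convolution for ST), and a
damped-Newton junction solve enforcing flow conservation and pressure
continuity together with the outgoing Riemann invariants (scaled residual
< 10⁻¹⁰). The WK capacitor uses the trapezoidal rather than a backward-Euler
update: both are unconditionally stable, but only the second-order rule
meets the 10⁻⁶ accuracy demanded of the step-response check at
$\Delta t = 10^{-4}$ s.

The inflow stand-in is
$q_\mathrm{in}(t) = Q_\mathrm{max}\sin^2(\pi t/(sT))$ during systole
(fraction $s$ of the cycle) and zero in diastole — a smooth two-parameter
surrogate for a measured main-pulmonary-artery flow, with murine-scale
defaults $T = 0.11$ s, $s = 0.45$, $Q_\mathrm{max} = 0.5$ ml/s. Each
simulation cycles until the root pressure waveform changes by at most 0.05
mmHg between cycles (at most 30 cycles), warm-starting the terminal states
at their DC operating points so the periodic state is typically reached in
3–8 cycles. The output is the root pressure at $m = 32$ uniform samples of
the converged cycle.

Fixture networks (1, 3 and 7 vessels at murine radii 0.025–0.05 cm) stand in
for an image-based 21-vessel pulmonary tree whose geometry is not bundled;
any tree can be supplied as a CSV (`id,parent,length_cm,r0_cm`).

# Designs and emulators

Designs come from the unscrambled base-2 Sobol sequence (Joe–Kuo direction
numbers, Gray-code construction) with the all-zeros point skipped — the most
common textbook convention, fully deterministic without a seed. Validation
and test blocks literally continue the training sequence. Default parameter
bounds: stiffness parameters at ±50% of nominal, WK scale factors in
[0.5, 2], ST factors $\alpha \in [0.80, 0.92]$, $\beta \in [0.55, 0.70]$,
$\ell_{rr} \in [10, 50]$, $r_\mathrm{min} \in [0.001, 0.01]$ cm — plausible
murine ranges, recorded in every design sidecar. Emulation uses the reduced
parameter subsets $\{k_1, k_2, r_p, r_d, c_T\}$ (WK) and
$\{k_1, k_2, \alpha, \ell_{rr}\}$ (ST) identified by total-order Sobol
screening (retention threshold 0.05, configurable).

The waveform matrix is reduced by PCA: column-mean removal, SVD of the
centered matrix with $1/(n-1)$ covariance normalization, $q = 5$ components
(which capture > 99% of variance on the simulator's output), and a
deterministic sign convention (largest-magnitude entry of each basis column
positive).

**GP.PCA** fits an independent zero-mean GP to each score, inputs scaled to
the unit cube, scores standardized to zero mean and unit variance (the
variance scaling is a recorded bijection that cannot change predictions).
Kernels: squared exponential, Matérn 3/2 and 5/2, arcsine neural-network,
optionally with automatic relevance determination; a fixed jitter from
$\{10^{-4},\dots,10^{-9}\}$ is added to the covariance diagonal.
Hyperparameters maximize the marginal likelihood by L-BFGS from five
deterministic low-discrepancy starting points in log space. **GP.time** adds
time as an input and imposes a separable covariance
$k_t(t,t')\,k_\theta(\theta,\theta')$, so the $nm \times nm$ covariance is
the Kronecker product of an $m \times m$ and an $n \times n$ factor (jitter
added to each factor's diagonal); likelihood and solves go through the two
small eigendecompositions and the full matrix is never formed. The periodic
time kernel's period is pinned to the cardiac cycle rather than learned —
it is physically forced, and learning it only adds a degeneracy.

**PCE.time / PCE.PCA** expand the output in orthonormal Legendre polynomials
of total degree $\le K$ on the bound-mapped cube $[-1,1]^d$
($J = \binom{d+K}{K}$ terms), coefficients per time point or per score by
ordinary least squares. The solver is SVD-based rather than the literal
normal-equations inverse — equivalent in exact arithmetic, stable when
$n \approx J$; when $n < J$ the minimum-norm solution is returned with a
prominent warning, the regime in which high-order PCEs collapse on small
training sets. The orthonormal basis makes Sobol indices sums of squared
coefficients; generalized indices aggregate over outputs weighted by
per-output variance.

The comparison pipeline (`run_study`) selects, per variant, the candidate
with the lowest median validation MSE (ties: smaller IQR, then candidate
order), reports per-test-point forward MSE, and solves the inverse problem
by bound-constrained L-BFGS-B (the R analogue of a sequential-quadratic
bound-constrained optimizer) from 20 maximin-Latin-hypercube starts drawn
with a fixed seed, re-running the true simulator at each estimate for the
simulator-based MSE, the summed relative square error (RSE) and
per-parameter absolute relative errors (ARE).

# Problem sizes and what the tests show

The bundled checks run at desk scale: training sizes 20 and 100 (standing in
for the 100 vs 1000 contrast), validation and test blocks of 10, the
3-vessel fixture, and candidate grids of one GP kernel pair (Matérn 5/2 with
ARD) and PCE orders 1–3. At these sizes the qualitative phenomena are
clear-cut: forward and inverse errors drop by one to two orders of magnitude
with the larger training set, PCE order 3 ($J = 56$) collapses on 20
training points while behaving well on 100, and GP emulators match or beat
PCE ones at equal training size. Inverse self-consistency (recovering the
exact parameters of an emulator-generated target) is checked on a
well-conditioned two-parameter subproblem, where the multistart optimizer
recovers the truth to machine precision; on the full five-parameter space
single-waveform inversion is genuinely ill-conditioned (stiffness and
resistance trade off) and only the output-space error is expected to be
small.

The synthetic generator emulates the study conditions, not any measured
animal: a parametric inflow instead of a measured flow trace, toy trees
instead of an image-based 21-vessel geometry, and noise-free outputs.
Passing tests therefore demonstrate correctness of the numerics and the
relative behaviour of emulators on this model family, not agreement with
any particular experimental recording.

# Known limitations

Single-phase Newtonian blood, elastic (not viscoelastic) walls, constant
per-vessel radius, no stenoses or gravity; impedance trees are linearized.
GP predictive variances are computed nowhere because the study's metrics use
predictive means only. The embedded Sobol direction table covers 21
dimensions, ample for the 10-parameter ST space.
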