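# pwemu — emulation of 1D pulmonary pulse-wave propagation models

`pwemu` is an R package for building and comparing fast statistical
surrogates ("emulators") of a one-dimensional haemodynamics simulator of the
pulmonary arterial circulation. Simulating pulse-wave propagation through a
network of compliant vessels is too slow for real-time, patient-specific
inverse problems; emulators trained on a modest number of simulations can
predict pressure waveforms in milliseconds and make parameter estimation
practical. The package is aimed at researchers in cardiovascular modelling
and surrogate-based uncertainty quantification.

## What is inside

* **Simulator** — the 1D cross-section-averaged blood-flow equations

  ∂A/∂t + ∂q/∂x = 0,  ∂q/∂t + ((γ+2)/(γ+1)) ∂(q²/A)/∂x + (A/ρ) ∂p/∂x = −2πμ(γ+2)/ρ · q/A

  solved by a Richtmyer two-step Lax–Wendroff scheme on bifurcating vessel
  trees, with wall law Eh/r₀ = k₁e^(−k₂r₀) + k₃ and either three-element
  Windkessel (RCR) or structured-tree impedance outflow conditions. The
  output of one run is the main-artery pressure waveform f(θ, t) at m = 32
  samples of a converged cardiac cycle.
* **Designs** — deterministic unscrambled Sobol sequences mapped to the
  biophysical parameter bounds, with train/validation/test blocks taken as
  one continued sequence (`make_design`).
* **Output reduction** — PCA of the m × n training waveform matrix
  (`fit_pca`); five components capture > 99% of the simulator's output
  variance.
* **Emulators** — four variants: independent GPs on PCA scores (`GP.PCA`),
  a time-input GP with Kronecker-separable covariance (`GP.time`), and
  Legendre polynomial-chaos expansions fitted by ordinary least squares per
  time point (`PCE.time`) or per score (`PCE.PCA`).
* **Sensitivity analysis** — first- and total-order generalized Sobol
  indices computed directly from PCE coefficients (`sobol_from_pce`).
* **Comparison pipeline** — `run_study` trains all variants over candidate
  hyperparameter grids, picks the lowest-median-MSE candidate on validation
  data, scores forward emulation on test data, and solves the inverse
  problem (multistart bound-constrained optimization of the emulator MSE),
  re-running the simulator at each estimate.

## Worked example

```r
library(pwemu)

# wall stiffness at the root radius (mmHg)
stiffness(0.05, wall_model())
#> [1] 22231.3

# simulate the nominal Windkessel model on the 3-vessel fixture
wf <- simulate_waveform(NULL, fixture_network("bifurcation3"),
                        simulation_config())
wf$converged; wf$cycles_used
#> [1] TRUE
#> [1] 6
round(range(wf$p), 2); round(mean(wf$p), 2)
#> [1]  9.86 44.59
#> [1] 20.13

# a 30-point Sobol design over the full parameter space, simulated and
# reduced to 5 principal components
sp  <- default_parameter_space("WK")
des <- make_design(sp, n_train = 28, n_valid = 1, n_test = 1)
ws  <- batch_simulate(design_block(des, "train"),
                      fixture_network("bifurcation3"), simulation_config())
pca <- fit_pca(ws$F, q = 5)
round(100 * pca$var_explained, 5)
#> [1] 99.99999
```

The simulated waveform is a murine-scale pulmonary pressure pulse
(diastolic ≈ 10 mmHg, systolic ≈ 45 mmHg, mean ≈ 20 mmHg), converged to a
periodic state in 6 cycles; across a space-filling design of simulations the
five leading principal components explain essentially all waveform variance,
which is what makes the reduced-space emulators competitive.

A full desk-scale comparison study is one call:

```r
st <- run_study(n_train = 20, n_valid = 10, n_test = 10, seed = 1)
st$variants$GP.PCA$selection$id       # winning candidate
st$variants$GP.PCA$forward$median     # median test MSE (mmHg^2)
```

## Vignette

`vignettes/methods.Rmd` documents the model equations and assumptions, the
numerical scheme and its tolerances, all tunable parameters with units and
defaults, the design decisions taken where conventions differ, and what the
desk-scale tests do and do not demonstrate.
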