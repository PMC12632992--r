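# spindlescale

Simulation and quantification of mitotic spindle elongation and chromosome
segregation in early embryonic cells, for cell biologists and biophysicists
studying how the division machinery scales as cells get smaller.

As an embryo divides, each cell is roughly half the volume of its parent,
yet every spindle must segregate the same chromosome mass. Spindle
*elongation* is driven by cortically anchored dynein pulling on astral
microtubules and therefore scales with cell size; chromosome *segregation*
is driven by mid-spindle microtubules and barely changes. `spindlescale`
implements both the model and the measurement layer behind this picture:

* **Stoichiometric cortical-pulling model.** Two asters in a spherical cell
  of radius R; cortical motors bind at most one microtubule each, giving a
  bound-probability surface field
  `dP_i/dt = Ω_i (1 − P1 − P2) − κ P_i`, a pulling force
  `F_i = (M f0 / A) ∫ P_i ξ̂ dA`, and overdamped pole motion
  `η ẋ_i + ν ((ẋ_i − ċ_i)·ŝ) ŝ = F_i` with a viscous pole–chromosome
  coupling. Chromosome separation is imposed as
  `Δc(t) = c_f (1 − e^{−t/τ_c})` (c_f = 6.2 µm, τ_c = 29 s). The
  microtubule catastrophe rate λ is the single stage-dependent parameter;
  `celegans_stages()` carries the six reference stage configurations
  (2- to 64-cell).
* **Catastrophe-rate inference** by differential evolution (rand/1/bin,
  50 simulations per generation, λ ∈ [0.001, 10]) against a target
  pole-to-pole trajectory, minimizing `Σ (L_exp − L_sim(λ))²`.
* **Trajectory quantification**: sigmoid fits of pole-to-pole traces
  (final length FLPP = L1 + L2, elongation rate ERPP = 60·L2/(4τ) µm/min),
  exponential fits of chromosome traces (FLCC = a, SRCC = 60·a/k),
  log-log scaling regressions versus cell size (cube root of volume),
  piecewise elongation-rate transition fits, one-way ANOVA F, stage
  averaging.
* **Kymograph readout**: prominence-based peak detection plus sub-pixel
  Gaussian refinement (`a·e^{−((x−b)/c)²} + d`), pole-bounded chromosome
  tracking, anaphase-onset detection.
* **Laser-ablation analysis**: windowed velocity fits, (−8, 0) s before and
  (4, 12) s after the cut, and pole/chromosome response summaries.
* **Electron-tomography classification** of traced microtubules into
  interpolar / mid-spindle / other by end-point geometry.
* **Synthetic-data generators** (trajectory atlases, two-channel
  kymographs, ablation cohorts, microtubule trace sets) so every stage of
  the pipeline is testable without external data.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_trajectories()` figures.

## Worked example

Quantify a synthetic 8-cell trajectory, then recover the 64-cell
catastrophe rate from a simulation's own pole-to-pole output:

```r
library(spindlescale)

# one noisy 8-cell trajectory from the synthetic atlas generator
cell <- gen_atlas(stages = 8, cells_per_stage = 1, seed = 42)$trajectories

fit_sigmoid(cell)
#> <sigmoid_fit> L1 = 2.759 um  L2 = 8.512 um  t0 = -1.06 s  tau_s = 36.23 s
#>   FLPP = 11.272 um  ERPP = 3.524 um/min  (rss 1.408, n 25)

fit_exponential(cell)
#> <exp_fit> a = 6.430 um  k = 30.78 s
#>   FLCC = 6.430 um  SRCC = 12.536 um/min  (rss 0.8699, n 25)

# simulate the 64-cell stage (R = 7.3 um, lambda = 0.945/s) and re-infer
# the catastrophe rate from the trace alone
stages <- celegans_stages()
traj <- simulate_spindle(stages[6, ])
fit_exponential(traj)
#> <exp_fit> a = 6.200 um  k = 29.00 s
#>   FLCC = 6.200 um  SRCC = 12.828 um/min  (rss 1.578e-30, n 30)

de <- de_config(population_size = 20, max_generations = 12, seed = 101)
fit_catastrophe_rate(traj, stages[6, ], de = de, n_patches = 128)
#> <catastrophe_fit> stage 64: lambda_hat = 0.9491 1/s  error = 0.02479 um^2  (12 generations, seed 101)
```

The sigmoid fit estimates the 8-cell spindle's final pole-to-pole length
(FLPP ≈ 11.3 µm, truth 11.2) and elongation rate (ERPP ≈ 3.5 µm/min); the
exponential fit of the simulated chromosome trace recovers the imposed law
exactly (final separation 6.2 µm, time constant 29 s); and differential
evolution, given only the simulated pole-to-pole trace, recovers the
generating catastrophe rate 0.945/s to within about 0.4%.

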