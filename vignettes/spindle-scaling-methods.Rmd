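---
title: "Methods: the stoichiometric spindle model and its quantification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stoichiometric spindle model and its quantification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spindlescale)
```

## The scientific problem

During early embryonic development cells halve in volume at every division,
yet the mitotic spindle must keep segregating the same chromosome mass. Two
distinct force systems are at work: spindle *elongation* is driven by
cortically anchored minus-end-directed motors pulling on astral microtubules,
and is therefore sensitive to cell geometry, while chromosome *segregation*
is driven by mid-spindle microtubules and is largely independent of cell
size. `spindlescale` implements a quantitative version of this picture: a
stoichiometric model of cortical pulling that predicts pole dynamics as a
function of cell radius and microtubule catastrophe rate, plus the
measurement layer (trajectory fits, kymograph readout, ablation windows,
tomography classification) used to confront such a model with imaging data,
and seeded generators for every input so the whole pipeline is testable
without external data.

## The model

Two asters sit in a spherical cell of radius $R$ (the cube root of the
measured mean cell volume at a given stage). Microtubules nucleate at each
centrosome at rate $\dot n = N_T \lambda$, grow at $V_g$, and undergo
catastrophe at rate $\lambda$, so the mean astral microtubule length is
$V_g/\lambda$. Motors of size $r$ are distributed uniformly on the cortex at
density $\rho$; each motor binds at most one microtubule (stoichiometric
binding), pulls with force $f_0$ along the microtubule toward the
centrosome, and unbinds at rate $\kappa$.

The bound-motor state is coarse-grained into a surface field $P_i(Y, t)$,
the probability that a motor at cortical position $Y$ is bound to a
microtubule from aster $i$:

$$\partial_t P_i = \Omega_i(Y, t)\,\bigl(1 - P_1 - P_2\bigr) - \kappa P_i,$$

where the shared free fraction $(1 - P_1 - P_2)$ is what makes binding
stoichiometric and creates competition between the asters. The pulling force
on pole $i$ is the surface integral

$$F_i = \frac{M f_0}{A} \int P_i(Y)\, \hat\xi(x_i, Y)\, dA,
\qquad M = \operatorname{round}(\rho A),\; A = 4\pi R^2,$$

with $\hat\xi$ the unit vector from the pole to the cortical point. Pole
motion is overdamped, with cytoplasmic drag $\eta$ and a viscous element
$\nu$ coupling each pole to its chromosome plate along the spindle axis
$\hat s = (x_1 - x_2)/\lVert x_1 - x_2\rVert$:

$$\eta \dot x_i + \nu\,\bigl((\dot x_i - \dot c_i)\cdot\hat s\bigr)\hat s = F_i.$$

Chromosome separation is not modeled mechanistically; it is *imposed* as
$\Delta c(t) = c_f (1 - e^{-t/\tau_c})$ with $c_f = 6.2\,\mu m$ and
$\tau_c = 29\,s$, the exponential law that describes measured segregation
and is nearly invariant with cell size. The plates ride the instantaneous
pole midpoint, separated by $\Delta c(t)$ along $\hat s$.

### The impingement kernel

The rate at which microtubules from aster $i$ reach a motor at distance $d$
is modeled as

$$\Omega(d) = N_T \lambda \cdot \frac{r^2}{4 d^2} \cdot e^{-\lambda d / V_g}:$$

nucleation supplies $N_T\lambda$ microtubules per second, an isotropic
emitter places fraction $\pi r^2 / 4\pi d^2$ of them on the motor's capture
cross-section, and a microtubule survives to length $d$ with probability
$e^{-\lambda d/V_g}$. `impingement_rate()` is the single place to swap in an
alternative kernel. Two consequences of this closed form matter in practice:

* **Non-monotonicity in $\lambda$.** Because the nucleation flux carries a
  factor $\lambda$, $\Omega$ *increases* with $\lambda$ when
  $\lambda < V_g/d$ and decreases only in the short-microtubule regime
  $\lambda d / V_g \gg 1$. Final spindle length inherits this: it peaks at
  intermediate $\lambda$ and decreases with $\lambda$ only in the tail. The
  monotonicity test therefore uses a grid inside the short-microtubule
  regime.
* **Near-cortex stiffness.** $\Omega \propto d^{-2}$ grows steeply as a pole
  approaches the cortex (tens per second within a couple of microns), so
  intermediate catastrophe rates at small stages can pull poles into
  near-contact where the explicit field update becomes unstable. Such
  parameter pathologies abort with an explicit error, and the
  differential-evolution objective scores them as infinitely bad.

### Default parameters

| parameter | symbol | default | units |
|---|---|---|---|
| microtubules per aster | $N_T$ | 5000 | — |
| growth velocity | $V_g$ | 1 | µm/s |
| catastrophe rate | $\lambda$ | per stage (0.038–0.945) | 1/s |
| motor density | $\rho$ | 0.12 | 1/µm² |
| motor size | $r$ | 1.5 | µm |
| detachment rate | $\kappa$ | 1/20 | 1/s |
| motor force | $f_0$ | 5 | pN |
| pole drag | $\eta$ | 450 | pN·s/µm |
| pole–plate coupling | $\nu$ | 50 | pN·s/µm |
| final separation | $c_f$ | 6.2 | µm |
| separation time constant | $\tau_c$ | 29 | s |

Per-stage cell radii, initial pole separations and reference catastrophe
rates are in `celegans_stages()`; everything else is held fixed across
stages.

## Numerics

* **Surface quadrature.** `build_cell_mesh()` places patches on a
  generative-spiral (Fibonacci) lattice, antipodally symmetrized — half the
  patches are spiral points, half their antipodes — so mirror-symmetric pole
  configurations experience exactly mirror-symmetric forces and the pole
  pair's center of mass stays at the cell center to machine precision. All
  patches carry area $4\pi R^2/n$; the default $n = 2000$ changes the
  cortical force by well under 1% on doubling, and meshes below 128 patches
  are rejected.
* **Time stepping.** Both the field and the poles advance by an explicit
  first-order update in this order: impingement rates from the current
  poles, field update, forces from the updated field, pole update (parallel
  component $(F_\parallel + \nu \dot c_\parallel)/(\eta + \nu)$,
  perpendicular $F_\perp/\eta$, with $\dot c_\parallel = \pm \tfrac12
  \,d\Delta c/dt$ from the analytic derivative of the imposed law). The
  field update is stable only while $\Delta t\,(\max\Omega + \kappa) < 1$;
  violations abort naming the offending step. The default $\Delta t =
  0.01$ s satisfies the guard with margin at all six reference stages,
  where near-cortex impingement rates reach ~70/s; the compiled and pure-R
  engines implement the identical update order and agree to 1e-12.
* **Sampling and horizon.** Output is sampled every 10.3 s (the acquisition
  interval of the imaging the pipeline emulates) to $t_{end} = 300$ s,
  about ten chromosome time constants, which covers the elongation plateau
  at every stage.
* **Chromosome midpoint.** The imposed law fixes only the separation
  magnitude; where the plate pair sits is open. The plates are pinned to the
  instantaneous pole midpoint, which keeps the spindle internally consistent
  under any pole drift; alternatives (pinning to the cell center, or free
  plate dynamics) would need forces the model does not represent.
* **Force direction.** $\hat\xi$ points from the pole to the cortex, per the
  model's description of motors pulling the centrosome toward their anchor.
  A useful check of the quadrature: for a *uniform* bound field the integral
  of $\hat\xi$ over the sphere points back toward the center (it is
  $-\nabla_x \int \lVert Y - x \rVert\, dA$, and the mean pole-to-surface
  distance $R + a^2/3R$ grows with displacement $a$), so elongation is
  driven entirely by the impingement asymmetry of the bound field, not by
  the uniform component. The test suite pins the quadrature against a 1-D
  integral oracle of this case.
* **Spindle axis.** $\hat s$ is computed from pole positions (velocities
  would be undefined at $t = 0$).

## Catastrophe-rate inference

The catastrophe rate is the single stage-dependent parameter, recovered by
minimizing
$\mathcal{E}(\lambda) = \sum_i \bigl(L_i^{exp} - L_i^{sim}(\lambda)\bigr)^2$
over the target's time points (simulated pole-to-pole distance linearly
interpolated to them). The search uses differential evolution, rand/1/bin,
over $\lambda \in [0.001, 10]$: population 50 (i.e. 50 simulations per
generation), mutation 0.7, crossover 0.9 (immaterial for a single gene),
convergence when the population's $\lambda$ spread falls below $10^{-3}$ or
after `max_generations` (default 25). A seed is mandatory and makes the fit
fully deterministic. Inside the DE loop simulations run on a reduced mesh
(256 patches by default; the quadrature converges fast enough that even 128
patches biases the objective negligibly) at the same $\Delta t = 0.01$ s
required by the stability guard; the reported error is re-evaluated with a
final full-resolution simulation. Candidates whose simulation aborts
(parameter pathology) score $+\infty$ and are simply rejected; an entirely
infeasible initial population is an error.

## Trajectory quantification

Pole-to-pole traces are fit with the four-parameter sigmoid
$f(t) = L_1 + L_2 / (1 + e^{-(t - t_0)/\tau_s})$; the derived quantities are
the final length $FLPP = L_1 + L_2$ and the elongation rate at the
inflection, $ERPP = 60\,L_2 / (4 \tau_s)$ in µm/min (the × 60 conversion is
pinned by unit tests). Chromosome traces use
$f(t) = a(1 - e^{-t/k})$ on post-onset samples, with $FLCC = a$ and
$SRCC = 60\,a/k$. Starting values come from the data (first sample, range,
half-range crossing, steepest finite-difference slope; for the exponential,
the last sample and the $1 - 1/e$ crossing), with a deterministic
multi-start over ±50% perturbations on non-convergence; fits that still fail
are returned flagged, and numerically flat inputs return degenerate flat
fits rather than errors.

Scaling regressions are ordinary least squares of $\log(\text{quantity})$ on
$\log(\text{cell size})$, reading "slope" as a power-law exponent — the
interpretation consistent with a ~2-fold length change over a ~3-fold size
change giving an exponent near 0.75; a linear-axes option is exposed and the
convention is recorded in the result. Cell size is always the cube root of
cell volume. The elongation-rate transition is a continuous two-segment fit
(flat at a plateau above the breakpoint, linear below); the breakpoint is
profiled over a grid augmented with the observed sizes — the remaining
parameters are linear given the breakpoint, so each profile point is solved
exactly — then refined locally, and fits that do not improve on a flat model
are flagged degenerate. The one-way ANOVA F statistic is
$MS_{between}/MS_{within}$ with the standard degrees of freedom, checked
against `stats::aov` on random inputs. Stage averages interpolate every
cell onto a common 10.3-s grid covering the overlapping time range and
report pointwise means and sample SDs.

## Kymograph readout

Kymographs are intensity matrices (frames × position along the spindle
axis). Per frame, the two spindle poles are located as the two most
prominent local maxima — the prominence floor is 3× the profile's median
absolute deviation, a robust noise estimate, since no detection settings are
inherited — with ties broken toward the profile center, then refined to
sub-pixel centers by least-squares Gaussian fits of
$f(x) = a\,e^{-((x-b)/c)^2} + d$. Note the width convention: the exponent
carries no factor 2, so $c$ is $\sqrt 2$ times the conventional Gaussian
sigma. Chromosome plates are then detected within the interval bounded by
the poles; before plate separation the chromosome signal is a single merged
peak, which is used for both plates (zero separation). Frames whose
detections fail carry missing values — positions are never fabricated — and
flagged frames never contribute to downstream fits. Pixel coordinates are
0-based; centers are continuous. Distances between voxel coordinates use the
anisotropic Euclidean form with voxel size (0.1, 0.1, 0.5) µm by default.
Anaphase onset is the last frame before the separation series exceeds its
pre-rise baseline (median + 3 MAD) for at least two consecutive frames.
Building kymographs from raw volumetric images is out of scope; the module
starts from the kymograph matrix.

## Ablation analysis

Pole and chromosome responses to spindle severing are quantified by
ordinary-least-squares velocities over fixed windows around the cut: (−8, 0)
s before and (4, 12) s after, both open intervals, which excludes the 0–4 s
severing/recoil transient by construction. The response object reports
before/after velocities for pole-to-pole and chromosome-to-chromosome
distances, their differences, and the percent change of the pole elongation
rate. Windows with fewer than three samples are flagged rather than
extrapolated.

## Tomography classification

Traced microtubules are classified by end-point geometry against the two
centrioles and the two chromosome-plate planes (each a centroid sharing the
spindle-axis normal): *interpolar* if either end lies within `pole_radius`
of a centriole (default 0.5 µm — no threshold is inherited, so it is an
exposed parameter), *mid-spindle* if both ends fall strictly inside the open
slab between the plate planes and neither end is pole-proximal, *other*
otherwise. Pole proximity takes precedence, so a microtubule running from a
pole through the nearer plate toward the other plate is interpolar. The slab
(rather than, say, a convex hull of the chromosomes) is the assumed reading
of "between the chromosomes". Classification is rigid-motion invariant and
counts always sum to the number of traces.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its configuration and a mandatory
seed. The atlas generator emulates the statistical structure the analyses
assume: an ellipsoidal embryo (length × width × width, defaults 51 × 30 ×
30 µm for the wild-type condition; 62 and 37 µm lengths mimic the enlarged
and reduced conditions) whose cells halve in volume per division; final
spindle length following a strong power law of cell size (default exponent
0.75) and chromosome separation a weak one (default 0.09), both anchored at
the 8-cell scale (11.17 µm final length and 6.2 µm final separation at 14
µm cell size, with a 2.97 µm/min elongation-rate plateau); a rate transition
at 12 µm; sampling at 10.3 s; additive Gaussian measurement noise (default
SD 0.2 µm) and 5% cell-to-cell parameter variation. Kymographs carry
Gaussian peaks with Poisson-like noise (variance proportional to the mean);
ablation records have a pole-velocity jump (default ×1.4, a >30% rate
increase) with invariant chromosome velocity, plus matched controls; the
tomography generator constructs traces with exact class membership.

What the generators deliberately do **not** reproduce: lineage-specific
volume asymmetries (divisions halve volume exactly), photophysics beyond the
simple noise models, spindle rotation or off-axis geometry, and any coupling
between neighboring cells. Passing round-trip tests therefore demonstrates
that the estimators recover the structure they assume, with correct units
and conventions — not that real embryos satisfy those assumptions.

## Problem sizes in the test suite

Unit tests run simulations on reduced meshes (128–256 patches) and short
horizons (up to 200 s); the end-to-end checks use the full defaults for the
six reference stages, and inference tests run differential evolution with
populations of 12–20 over up to 20 generations on 128-patch meshes, with
per-stage time steps sized to the stability guard (larger cells tolerate
larger steps) and horizons covering each stage's elongation rise — sizes at
which the recovery tolerances quoted in the tests hold. The synthetic atlas
defaults to 100 cells per stage.

## Known limitations

* The impingement kernel is a first-principles stand-in; the constant in
  front of $r^2/4d^2$ is the one modeling choice not pinned by data, and
  absolute simulated lengths (and hence the fitted scaling exponent across
  stages) inherit it. The pipeline treats it as swappable.
* Motors are a deterministic mean field: no binding noise, no discrete
  motor count effects beyond the $M f_0 / A$ prefactor.
* Only spherical cells; no cortical repulsion near the boundary (none is
  part of the model, so poles can legitimately approach the cortex).
* Chromosome dynamics are imposed, not predicted; the model cannot speak to
  mechanisms of segregation, only to its insensitivity to pole forces.
* Single-parameter inference: motor density, forces and drags are held at
  their reference values rather than jointly fit, and uncertainty is
  assessed only by seed replication.
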