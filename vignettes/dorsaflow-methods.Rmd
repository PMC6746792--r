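---
title: "Measuring dorsal cell mechanics from bead trajectories in channel flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dorsal cell mechanics from bead trajectories in channel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsaflow)
```

## The measurement platform

Adherent cells are grown on the floor of a shallow rectangular microfluidic
channel (1 mm wide, 100 µm high) and decorated with 2.8-µm ligand-coated
beads that bind receptors on the cells' *dorsal* (upper, non-substrate)
surface. A syringe pump drives medium through the channel; the drag on each
cell-bound bead is set by the flow rate, spanning roughly 14 pN at
10 µl/min to about 2 nN at 1400 µl/min. Time-lapse bright-field imaging at
low magnification follows up to ~50 beads at once, and every readout of the
platform is a reduction of those bead trajectories:

* **Traction mode** (weak flow): cells pull beads *against* the flow at
  constant speed; the traction force is read from the force balance.
* **Viscoelastic mode** (strong constant flow switched on and off): bead
  displacement follows a creep-and-recovery curve fitted by a four-element
  viscoelastic model.
* **Bond-strength mode** (step-wise flow ramp): beads detach when the
  applied force exceeds the strength of the receptor–ligand bond cluster;
  attachment counts per step give a survival curve and a rupture force.

The package implements all three reductions, the hydrodynamic force
calibration they share, synthetic generators with ground truth for each
mode, and a minimal spot tracker for synthetic image stacks.

## Hydrodynamic calibration

### Flow model

The channel has a 10:1 width-to-height aspect ratio and only cells more
than 200 µm from the side walls are analysed, so in the measurement region
the laminar velocity profile is the parallel-plate (plane Poiseuille)
solution

$$u(z) = 6\,\bar u\,\frac{z}{H}\Bigl(1 - \frac{z}{H}\Bigr), \qquad
  \bar u = \frac{Q}{wH},$$

with no-slip at floor and ceiling. `channel_velocity()` implements this
profile; mass conservation ($\int_0^H u\,dz \cdot w = Q$) is verified by
quadrature in the tests. A full rectangular-duct series solution would
change the centre-region profile by well under a percent at this aspect
ratio and is deliberately not included.

### Particle transport

A bead advected at fixed height obeys

$$m\frac{dV_p}{dt} = \tfrac{1}{8}\pi\rho_f d_p^2 C_D\,
  \lvert V_f - V_p\rvert (V_f - V_p),$$

with the Schiller–Naumann drag coefficient
$C_D = (24/Re_p)(1 + 0.15\,Re_p^{0.687})$. For a 2.8-µm bead in water the
momentum relaxation time $m/(3\pi\mu d)$ is ≈0.6 µs, so the bead reaches
the local fluid velocity essentially instantly; `advect_particle()`
integrates the equation explicitly with a step equal to the relaxation
time (capped at 10 µs) and stops when the slip ratio falls below $10^{-4}$.
No lift, gravity or Brownian term is modelled: the calibration needs the
terminal velocity at a given height, and for these beads all three effects
are negligible on that quantity.

### Wall-corrected drag and the force–distance calibration

Near the channel floor the Stokes drag on a translating sphere rises by
the Faxén-type factor

$$C = \Bigl[1 - \tfrac{9}{16}r + \tfrac18 r^3 - \tfrac{45}{256} r^4
  - \tfrac1{16} r^5\Bigr]^{-1}, \qquad r = \frac{d}{2h},$$

where $h$ is the centroid height. Cell heights run 3–8 µm and $C$ varies
little over that band, so a universal reference height of $h = 5$ µm is
used (configurable); there $C = 1.185$ for a 2.8-µm bead. The applied
force is $F_A = 6\pi a \mu u C$, with the Schiller–Naumann multiplier
applied above $Re_p = 10^{-3}$ for continuity with the transport model.

`build_calibration()` evaluates the terminal-velocity drag on a grid of
nine heights (2–50 µm; the wall correction is evaluated per height) and
fits the four-parameter logistic

$$F(x) = \frac{A_1 - A_2}{1 + (x/x_0)^p} + A_2$$

by Levenberg–Marquardt least squares (five restarts with jittered $x_0$
under a fixed internal seed, best SSE wins, $p$ bounded in $(0, 10]$).
On the default grid the fit reaches $r^2 \approx 0.999$ at every flow
rate used by the assays; `applied_force()` evaluates it at an arbitrary
height and warns outside the calibrated span. Fluid properties default to
water at room temperature (µ = 1.0 mPa s, ρ = 1000 kg/m³); they are not
measured by the platform and are exposed in the configuration.

## Traction forces

A bead pulled against the flow at constant speed $u$ satisfies the scalar
magnitude balance along the flow axis

$$F_C = F_A + F_D, \qquad F_D = 6\pi a \mu_c u f(\theta),$$

where $F_D$ is the drag of the bead translating along the interface
between medium and cell cortex, $\mu_c$ is the cortical viscosity
(default 550 Pa s, itself obtainable from the creep fit) and

$$f(\theta) = \tfrac12\bigl[1 + \tfrac{9}{16}\cos\theta
  - 0.139\cos^2\theta\bigr]$$

is the interfacial drag coefficient at contact angle $\theta$. Beads are
about half-enveloped by the membrane, so the default is $\theta = \pi/2$,
where $f = 0.5$ exactly. Over $\theta \in [\pi/3, 2\pi/3]$, $f$ deviates
from $f(\pi/2)$ by up to ≈32%, which bounds the error of the right-angle
assumption; measuring $\theta$ is advisable when that error matters.

Speeds come from an ordinary least-squares line through the projected
displacement series (`estimate_velocity()`), with at least 5 samples
required and fits with $r^2 < 0.8$ flagged but never dropped — constant
velocity is an assumption the user should be able to audit. Motion *with*
the flow cannot be interpreted by the balance above and yields a flagged
result with $F_C$ unset; a stationary bead degenerates to $F_C = F_A$.
In the magnetic-tweezers comparison mode the applied force is calibrated
from free-bead speeds as $F_M = 6\pi a\mu u C$ and enters the identical
balance.

## Viscoelasticity

### Model

Bead displacement under a constant force step, expressed as a creep
compliance $J(t) = 6\pi a C\,X(t)/F_A$, is fitted by the four-element
(Burgers-type) model

$$J(t) = \frac{1}{G_0}\Bigl[1 - \frac{G_1}{G_0 + G_1}
  e^{-t/\tau}\Bigr] + \frac{t}{\mu'_0}, \qquad
  \tau = \frac{\mu'_1 (G_0 + G_1)}{G_0 G_1},$$

giving an instantaneous elastic jump $1/(G_0+G_1)$, delayed elasticity
with relaxation time $\tau$, and viscous flow $t/\mu'_0$. The flow
viscosity $\mu'_0$ and the delayed viscosity $\mu'_1$ are kept as two
independent parameters so that the four reported quantities
($E_0$, $E_1$, $\mu_0$, $\mu_1$) and $\tau$ are all separately defined;
a tied three-parameter variant ($\mu'_0 = \mu'_1$) is available via
`fit_kv4(tied = TRUE)` for comparison. Shear-form parameters are
converted with $E_i = 2G_i(1+\nu)$ at Poisson ratio $\nu = 0.4$
(configurable in $[0, 0.5]$).

### Fitting choices

* Displacements are referenced to the bead's mean position over the 10 s
  before flow onset. The bead is stationary before loading, so this
  suppresses the localisation noise of a single reference frame — which
  would otherwise enter *every* compliance value as a constant offset
  comparable to the elastic jump and systematically corrupt the fit.
* The frame recorded at flow onset precedes loading ($X = 0$ by
  construction) and is excluded from the fit, because the model's
  instantaneous compliance is finite.
* Parameters are fitted in log space (positivity by construction) with
  Levenberg–Marquardt, five restarts around data-driven starts
  (late-time line → $G_0$ and $\mu'_0$; early samples → $G_0+G_1$;
  half-rise → $\tau$) with progressively wider jitter under a fixed seed.
* Only the creep window is fitted. The recovery window is predicted by
  Boltzmann superposition, $X(t_{off}+t') \propto J(t_{on}+t') - J(t')$
  (`recovery_curve()`), and serves as an out-of-sample check; its
  long-time limit is the residual viscous displacement
  $F_A t_{on} / (6\pi a C \mu'_0)$.

### Identifiability of the delayed mode

The instantaneous/delayed split is only observable within a few $\tau$ of
flow onset. At the assay's 0.5 s frame interval and forces around 1–1.5 nN,
a cell with $G_0 + G_1 \approx 700$ Pa produces an elastic jump of ~70 nm
— about one localisation-noise standard deviation (50 nm) — and a
delayed transient of $\tau \approx 0.35$ s spanning barely one frame. A
Fisher-information calculation at exactly these conditions puts the
Cramér–Rao bound for $G_1$ above 100% relative error even at one tenth of
the noise; no unbiased estimator can resolve it. In practice least squares
then drifts along a near-flat ridge ($G_1 \to \infty$ with a compensating
$\tau$), and such solutions run to the optimiser's parameter box. They are
reported with `boundary = TRUE` and must be treated as "delayed mode not
identifiable", not as estimates. The well-identified quantities at these
conditions are $G_0$ (late-time elastic plateau, a few percent) and
$\mu'_0$ (terminal slope, sub-percent); resolving $G_1$, $\mu'_1$ and
hence $E_0+E_1$ requires either lower noise, a longer relaxation time, or
faster sampling. This is a property of the measurement conditions, not of
the fitting code: with noiseless synthetic data the fit recovers all four
parameters to better than 1%.

## Bond strength

The ramp protocol raises the flow rate from 200 to 1400 µl/min in
200 µl/min steps of 30 s each; a 60 s no-flow lead-in brings the recorded
window to 270 s and provides the ramp-start attachment count. A bead is
scored as detached during a step when its track ends within the step or
its within-step along-flow displacement exceeds 5 µm — far above any creep
displacement at these forces, so the rule is unambiguous: a detached bead
is swept downstream out of the field. `count_attached()` therefore returns
one count per step *start* plus a final post-ramp count, so that the loss
during every step, including the last, is attributable to that step's
force.

The rupture force is the step force with the largest fractional loss of
the surviving population, $(S_{k} - S_{k+1})/S_{k}$, with ties resolved to
the earliest step. It is reported as the step force itself — a lower bound
on the true threshold within the 30 s step; no interpolation between steps
is attempted, matching the step resolution of the protocol. A population
whose thresholds exceed the maximal ramp force shows up as a survival
plateau, not as a rupture event. Counts are pooled across replicates
before survival computation.

## Synthetic data

Each generator reproduces the statistical structure its assay assumes and
stores the exact per-particle truth:

* `gen_traction_tracks()`: constant speeds against the flow, log-normal
  across beads (median 20 nm/s, log-sd 0.3), 10 s frames for 300 s.
* `gen_creep_tracks()`: four-element creep plus superposed recovery,
  per-cell parameters log-normally scattered (log-sd 0.3, mean-preserving)
  around $G_0 = 500$, $G_1 = 200$ Pa, $\mu'_0 = 550$, $\mu'_1 = 50$ Pa s —
  so the cohort-mean instantaneous stiffness is ≈1.96 kPa at $\nu = 0.4$,
  the scale reported for real cells; 0.5 s frames for 180 s with the force
  window at 10–100 s.
* `gen_ramp_tracks()`: per-bead rupture thresholds from two-component
  mixtures; component sizes are fixed counts with log-normal scatter
  *within* components, so population fractions are exact by design rather
  than binomially noisy at n = 50. The "integrin"-like preset puts 27% of
  thresholds between the step-1 and step-2 forces and the rest above the
  maximal ramp force (sharp loss at step 2, then a plateau); the
  "cd80"-like preset puts 90% below the step-1 force (sharp loss at
  step 1). Beads detach at a uniform random time within the middle of the
  step whose force first exceeds their threshold.

Localisation noise is i.i.d. Gaussian with σ = 50 nm per frame per axis, a
plausible sub-pixel precision (~0.1 px) for bright-field tracking at 10X
with ~0.65 µm pixels; the platform's actual noise floor is not published,
so this default is an assumption and is exposed as a parameter. The
generators add no Brownian motion (bound beads' thermal displacement is
far below the noise floor at this bead size), no stage drift, no bead
aggregation and no cell-shape rendering. Consequently, passing recovery
tests demonstrate correctness of the inference given the model, not
robustness to those real-data artefacts; aggregated beads in real data are
handled by the user-supplied include-list, not detected automatically.

`gen_image_stack()` renders tracks as Gaussian spots with Poisson shot
noise into 16-bit stacks, and `detect_and_link()` (threshold → connected
components → intensity-weighted centroids → greedy nearest-neighbour
linking with a hard gate) recovers tracks from them; this minimal
front-end exists to exercise the pipeline end to end from pixels, not to
replace a production tracker: there is no gap closing, splitting, merging
or drift correction.

## Numerical and interface choices

* SI units internally everywhere; µl/min, µm and pN appear only at
  interfaces and in plots.
* Image coordinates: x/y in µm, origin top-left; the flow direction is a
  configuration input (it is known from the rig), never inferred.
* Frames are 0-based; time zero is acquisition start; flow-onset times
  come from the configuration.
* Track CSVs: TrackMate spot exports (`TRACK_ID`, `FRAME`, `POSITION_X/Y`,
  optional `POSITION_T`) or a generic dialect (`track`, `frame`, `time`,
  `x`, `y`); written files carry explicit times so they round-trip without
  external metadata.
* All stochastic components (generators, fit restarts) are seeded;
  identical configuration and seed reproduce byte-identical outputs.
* Test and example cohort sizes (e.g. 48 traction beads, 53- and 80-cell
  creep cohorts, 50-bead ramps) match the platform's per-experiment event
  counts, which also keeps the full suite fast.

## Limitations

* The force balance is scalar along the flow axis; 2-D vector balances,
  per-molecule force decomposition and contact-area stress conversion are
  out of scope.
* The calibration is semi-analytic: no entrance region, no particle-wall
  hydrodynamic coupling beyond the Faxén correction, no bead-bead
  interactions.
* The delayed viscoelastic mode is not identifiable at the standard assay
  conditions (see above); treat $G_1$, $\mu'_1$, $\tau$ and $E_0+E_1$
  from noisy single-bead fits with the `boundary` flag in hand.
* Rupture forces are multivalent bond-cluster strengths at step
  resolution; no loading-rate (Bell-type) extrapolation to single-molecule
  quantities is attempted.
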