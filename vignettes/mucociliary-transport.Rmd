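---
title: "Modelling mucociliary transport with ciliaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mucociliary transport with ciliaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ciliaflow)
```

## The physical model

Mucociliary clearance moves the airway's mucus blanket toward the throat by
the coordinated beating of cilia. `ciliaflow` simulates a two-dimensional
channel cross-section of this system:

* The **periciliary liquid (PCL)** is a Newtonian layer of depth 6.2 um in
  which the cilia beat.
* The **mucus layer (ML)** above it is an Oldroyd-B viscoelastic fluid with
  total viscosity 40 times the PCL's, split into a Newtonian solvent part
  (fraction Rv = 0.975, carried by the lattice-Boltzmann relaxation time)
  and an elastic part (fraction 1 - Rv, carried by an upper-convected
  Maxwell stress with relaxation time lambda = We T, We = 0.01).
* A **virtual elastic membrane** — an advected closed node-spring chain —
  separates the layers. It has no mechanical barrier function; it only
  partitions the material properties, so a single momentum solver covers the
  whole channel with a spatially varying viscosity map and an
  indicator-weighted elastic-stress force.
* **Cilia** (length L = 5.5 um, 20 Hz) are node-spring fibers clamped to the
  bottom wall. Each is dragged through per-node penalty springs by a
  prescribed **virtual cilium** whose posture table defines the beat; the
  spring force is `F_c = K_sl (Y - X)`.
* **Rigid particles** (0.4–0.8 um discs) couple to the fluid by
  direct-forcing penalty immersed-boundary exchange, with a short-range
  quadratic repulsion against walls, cilia and each other.

The fluid solver is a D2Q9 single-relaxation-time (BGK) lattice-Boltzmann
method with Guo forcing. All moving boundaries exchange force and velocity
with the lattice through regularized delta kernels (4-point Peskin kernel by
default). The channel is periodic in x, no-slip (halfway bounce-back) at the
bottom, and a free-slip wall at the top of the ML.

Mean ML transport is measured from passive tracepoints seeded at mid-ML
height: the mean unwrapped x-displacement over a 3T window after the flow
has developed, converted to um/s.

## Unit mapping and the flow regime

One lattice spacing is 0.1 um at full resolution (0.2 um in the reduced
`"half"` mode used for desk-scale checks) and one beat period is
`steps_per_T` time steps (4000 full, 2000 half). Three numerical-regime
choices deserve explanation, because the source model states targets
(Re = 0.05, coefficient values "in nondimensional units") without the
lattice scales that would pin them down:

**PCL viscosity.** The physical regime is creeping flow. On a lattice, the
achievable regime is bounded on two sides: the ML relaxation time
`tau_ML = 1/2 + 3 * 0.975 * 40 * nu_PCL` grows with the PCL viscosity
(BGK accuracy degrades for large tau), while a small `nu_PCL` lets
momentum accumulate over many beat periods in the periodic channel (the
array's thrust is only drained by bottom-wall friction over the viscous
diffusion time `H^2/nu`), which destabilizes the coupled system long before
any physical steady state. The default `nu_pcl = 1` makes cross-channel
momentum diffusion faster than half a beat period and keeps the cilium-tip
Reynolds number near 1; the nominal Re = 0.05 of the modelled regime is
recorded in the configuration and the effective lattice value is reported
as a diagnostic. The residual distance from the creeping-flow asymptote is
absorbed by the beat-amplitude calibration below, which anchors the
absolute transport scale.

**Spring coefficients.** The model's coefficients (K_s = 2, K_b = 1,
K_sl = 1) are nondimensional with an unstated force scale, so their lattice
values are part of the unit mapping. The mapping here is fixed by the
*documented behaviour* of the structures: cilia are near-inextensible and
track the virtual cilium synchronously. Two constraints shape the lattice
values: the explicit fluid-structure coupling is only stable while
(mobility x stiffness x operator norm) stays below a threshold, and the
penalty springs already enforce the beat shape, making a large bending
coefficient redundant. The defaults are extensional 8, bending 0.25,
penalty 1 for the cilium (membrane: 2 and 1, at its own node spacing).
With them, interior segment strains stay below 0.2% over a developed beat
and the tracking error is below 1% of L.

**Incompressible lattice.** The equilibrium is the He-Luo incompressible
variant (identical to the standard second-order equilibrium at unit
density). In a pressure-driven channel the standard compressible lattice
converts the streamwise pressure drop into a density drop and scales the
velocity with it — a ~19% error at the validation benchmark's parameters —
while the incompressible variant carries the pressure in the density field
without touching the velocity.

## The beat waveform and its calibration

The source model does not publish its beat postures, so the package
generates a two-stroke planar beat in tangent-angle form (postures are
integrals of a unit tangent, hence exactly inextensible, with a fixed
root): the **effective stroke** (fraction `beat_asymmetry = 0.3` of the
cycle) pivots the straight cilium through `2 * beat_amplitude` radians;
the **recovery stroke** returns it with a root-to-tip curvature wave of
width `wave_width * L`, keeping the tip low. The tip path encloses a
nonzero area, the requirement for net pumping at low Reynolds number.

During recovery the distal section additionally *reclines* toward the
wall (`beat_recline`), which keeps the return path low; the height
asymmetry between the strokes is what pumps at low Reynolds number.

The amplitude is the model's single calibrated quantity, following the
source's own procedure: at cilium spacing 0.55 L the mean ML velocity is
regulated to approximately 42 um/s. The calibrated default is
`beat_amplitude = 0.6` rad under the reduced measurement protocol
(half resolution, 10 T duration, tracer window = final 3 T), giving
41 um/s. Net transport is a near-cancellation of effective-stroke forward
pumping and recovery-stroke backward pumping; at appreciably smaller
amplitudes the recovery dominates and the net transport reverses. All
parameter sweeps therefore compare runs at the same calibrated
amplitude.

## Numerical choices

* **Metachronal closure.** Adjacent cilia carry phase offsets
  `k * phase_diff`. Under periodic boundaries the offsets must wrap
  consistently (`n_cilia * phase_diff` integer); otherwise the seam pair
  beats with a large phase jump, the two cilia physically collide, and the
  coupled system fails. The channel length is therefore snapped to the
  closure constraint by default (50 cilia for the reference 0.02 T offset).
* **Stress transport.** First-order upwind advection with an explicit
  source step; symmetry is structural (the off-diagonal component is
  stored once). A small artificial stress diffusion (`kappa = 0.005`)
  stabilizes the explicit transport at Weissenberg numbers of order 1; at
  the benchmark's We = 1 it biases the steady conformation profile by
  about 1%, and at the mucus layer's We = 0.01 its effect is negligible.
  A velocity inlet needs the incoming elastic stress prescribed
  (hyperbolic transport); the benchmark imposes the analytic developed
  stress there.
* **Layer map.** The ML indicator is a smoothed Heaviside of the height
  above the membrane polyline with a transition half-width of 0.2 um
  (2 nodes at full resolution), rebuilt every 4 steps (the membrane moves
  ~1e-3 nodes per step).
* **Wall closures.** Halfway bounce-back for the bottom no-slip wall.
  The top slip wall uses a non-equilibrium-extrapolation closure (free-slip
  velocity, neighbor non-equilibrium): at the mucus layer's large
  relaxation time a specular-reflection slip wall lets non-equilibrium
  noise accumulate and eventually destabilizes the layer, while the NEE
  closure stays regular. The validation benchmark also uses NEE no-slip
  walls, second-order accurate at its tau = 3.2.
* **Interface integrity.** Three safeguards keep the advected membrane a
  well-behaved material interface: its mean height is reprojected to the
  exact invariant of the continuous problem (the area below a material
  curve in a divergence-free field is conserved; the discrete interpolated
  field is not exactly solenoidal at the kernel scale and the curve would
  otherwise drift); a pre-tension (rest length 0.75 of the node spacing,
  interfacial tension ~0.7 in lattice units) suppresses soft
  long-wavelength undulations; and adjacent nodes are nudged apart when
  their x-gap closes below 0.2 nodes (folding prevention). The penalty
  driving force is capped at 1 per node, a regularization that only
  activates when out-of-phase neighboring cilia overlap.
* **Degenerate inputs.** Non-positive densities, non-finite fields and
  CFL violations abort with step diagnostics; membrane folding (loss of
  single-valuedness) aborts with a geometry message; beat tables with a
  moving root or a single phase are rejected at load time.

## What the synthetic data generator emulates

All inputs are generated: beat posture tables, fiber shapes with analytic
force oracles, closed-form flow fields (uniform, shear, Poiseuille,
decaying shear wave) and seeded trigonometric random fields for stencil
tests. The beat generator emulates the kinematics of an airway cilium
(asymmetric two-stroke cycle, near-inextensible postures); it does not
emulate measured ciliary waveforms, axonemal mechanics, or hydrodynamically
emergent metachrony (the phase pattern is prescribed, not self-organized).
Quantities tied to the absolute transport speed are therefore
calibration-dependent; trends across mucus thickness, cilia density and
phase difference are the model's meaningful comparisons.

## Problem sizes used by the checks

The validation benchmark runs the published 120 x 40 channel to steady
state (both We values finish within a minute). The reference transport
check runs the reduced mode — half resolution, 2000 steps per beat, 10
beat periods with the final 3 T as measurement window — and the
parameter-trend cells run 5 beat periods each (their per-period transport
series plateau within 3-4 beats); the particle studies run 6-20 T. These
sizes keep the whole verification suite on a single CPU within tens of
minutes; the full-resolution 30 T configuration is available through
`mcc_config(resolution = "full", duration_T = 30)`.

## Which published behaviours the desk-scale model reproduces

With the reduced protocol the package reproduces: the viscoelastic
Poiseuille closed forms (~1% profile errors at We = 0.01 and 1), the
calibrated reference transport speed, the strong enhancement of transport
with metachronal phase difference over the runnable range (0.02-0.075 T,
a five-fold increase), the mirrored-beat antisymmetry, and the particle
capture behaviour (0.4 um particles seeded at 4.5 um reach the cilia-tip
region within ~3.5 beats; particles seeded at 2 um stay confined between
the cilia).

Two published trends do not reproduce in this regime, and one is
truncated; the package reports them as measured rather than adjusting the
model toward the expected orderings:

* **Mucus thickness.** The measured steady transport increases with ML
  thickness. With a free-slip top wall the ML slides as a nearly frictionless
  slab whose steady speed is fixed by the zero-mean-shear condition at the
  PCL-ML interface, so nothing in the composed model slows a thicker layer;
  a decreasing trend would require measuring inside a spin-up-limited
  transient, which sits far outside the desk-scale time mapping.
* **Cilia density.** At the reference 0.02 T coordination, transport at
  the intermediate 0.78 L spacing reverses sign: the reclined recovery
  stroke of each cilium overlaps its neighbor's effective stroke, and the
  resonance is robust to the recovery-shape parameters. At 0.05 T
  coordination the three-point density trend is monotone increasing, so
  the density effect is entangled with the metachronal coordination in
  this regime.
* **Phase difference.** Offsets of 0.1 T and above are unrunnable at desk
  scale: widely out-of-phase neighbors sweep through each other with
  conflicting penalty targets and the explicit coupling fails within the
  first beat.

## Known limitations

* The tip-most two or three segments of a cilium carry a residual apparent
  strain of up to ~3% during the fastest stroke phase — a free-end artifact
  of the explicit penalty coupling (the end node's drag is not shielded by
  a neighbor). The interior of the fiber stays below 0.2%, so the
  near-inextensibility target of the node-spring model is met everywhere
  except at the free tip; the conservative run-maximum statistic reported
  by `run_mcc()` is dominated by this artifact.
* The two-layer lattice cannot reach the creeping-flow limit exactly (see
  the unit-mapping section); absolute transport speeds lean on the
  amplitude calibration, and measured speeds drift by a few percent per
  beat period at the end of a 10 T reduced run (the developed-flow detector
  reports the window used).
* The mucus rheology is Oldroyd-B: no shear-thinning, no finite
  extensibility, no yield stress.
* Particles are resolved with only ~2-4 lattice cells per diameter in the
  reduced mode; their coupling is a weak penalty exchange, adequate for
  migration trends but not for accurate drag or lubrication forces.

## A worked example

```{r example}
library(ciliaflow)

# viscoelastic Poiseuille validation (printed errors are relative L2)
bench <- run_poiseuille(We = 0.01)
bench

# reduced reference transport run
cfg <- mcc_config(resolution = "half", duration_T = 10)
run <- run_mcc(cfg)
run

# three-point thickness sweep
base <- mcc_config(resolution = "half", duration_T = 10)
sweep_thickness(base, thickness_um = c(4, 6, 8), spacing_L = 0.55)
```
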