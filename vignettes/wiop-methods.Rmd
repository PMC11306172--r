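---
title: "Energetics of non-contact tonometry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics of non-contact tonometry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiop)
```

## The problem

Non-contact tonometers estimate the intraocular pressure (IOP) by deforming
the cornea with an air jet and timing the instant at which the central
cornea becomes flat (first applanation). That reading confounds four
quantities: the IOP itself, the corneal material stiffness, the central
corneal thickness (CCT) and the jet force. `wiop` implements an energetic
alternative: it books the mechanical work done *on the anterior corneal
surface* by the internal fluid pressure and by the external load, and uses
the instant at which the two work curves intersect -- which coincides with
the maximum apex velocity and, unlike applanation, is insensitive to the
corneal material and thickness -- to map an apex-velocity trace to a
work-based pressure estimate (wIOP).

The package contains a complete reduced-order simulator of the test (so the
whole calibration chain can be re-derived on a desk) plus the clinical-facing
estimator, which needs only the apex-velocity trace that the device exports.

## The structural model

The globe is axisymmetric: a meridian chain of ring elements from the
corneal apex to the posterior scleral pole, revolved about the
anterior-posterior axis (`y`, positive outward through the apex). The
reference geometry intersects an anterior corneal sphere (radius 7.7 mm,
chord diameter 11.5 mm) with a scleral sphere (radius 12 mm); a 1 mm limbal
band straddles the junction. Only the CCT is taken from the sweep design
table; the remaining dimensions are package conventions exposed in
`eye_geometry_config()`.

Each element carries a nonlinear membrane response derived from the
regional strain-energy functions:

* **Cornea** -- fibre-reinforced (Holzapfel--Gasser--Ogden form):
  $\bar\Psi = C_{10}(\bar I_1-3) + \frac{k_1}{2k_2}\sum_{i=4,6}
  \left[e^{k_2(\bar I_i-1)^2}-1\right]$, with two mutually orthogonal
  collagen families. In the axisymmetric reduction the nasal-temporal /
  superior-inferior pair is represented by the in-surface orthogonal pair
  (meridional, circumferential), which preserves the total fibre content
  under the symmetry. Fibre terms are tension-only ($\bar I_i > 1$), the
  standard switch that prevents non-physical compressive stiffening.
* **Limbus** -- the same form with a single circumferential family.
* **Sclera** -- isotropic Neo-Hookean, $\bar\Psi = C_{10}(\bar I_1-3)$.

The wall is exactly incompressible in plane stress
($\lambda_3 = 1/\lambda_1\lambda_2$), so no volumetric penalty enters the
membrane and the stable time step is set by the in-plane tangent stiffness.
The separate `hgo_energy()` / `hgo_stress()` functions implement the full
three-dimensional law (isochoric split plus volumetric penalty
$U = K(J-1)^2/2$, $K \ge 10^3 C_{10}$) and are verified against numerical
energy gradients; the membrane elements use the same isochoric energy core.

**Bending.** A pure membrane cannot represent the flexural rigidity that a
solid-element wall has through its thickness, and that rigidity matters
here: without it the shallow corneal cap is so geometrically soft that the
zero-pressure recovery loses contractivity and the indented cornea can
kink. Every meridian node therefore carries a rotation-free bending hinge
with stiffness from the matrix modulus,
$D = E\,t^3/[12(1-\nu^2)]$ with $E = 6C_{10}$ and $\nu = 1/2$ (the apex
hinge uses its mirror image across the axis). Bending energy is part of the
wall strain energy, so the scheme remains exactly conservative.

**Humors.** The cavity enclosed by the wall is filled by an incompressible
fluid at the IOP, realised as a stiff, spatially uniform (hydrostatic)
pressure--volume law $P = P_0 + K_f (V_0-V)/V_0$ with $K_f$ = 5 MPa by
default -- stiff enough that the relative volume change stays well below
0.5% during loading, so an indentation of the cornea is absorbed by scleral
expansion and a pressure rise, as in the full model. The pressure load is
applied as the follower force $P\,\nabla_x V$, which makes the discrete
pressure power exactly $P\,\dot V$.

**Units.** Internally mm--g--ms--MPa (1 MPa·mm² = 1 N, energies in mJ);
clinical pressures convert at 1 mmHg = 1.33322e-4 MPa. Tissue density is
1.05e-3 g/mm³.

## Pre-stress: the zero-pressure configuration

The imaged geometry is already pressurised. `recover_zero_pressure()` finds
the stress-free configuration by the classic fixed-point pull-back
$X_0^{(k+1)} = X_0^{(k)} - \omega\,(x_{\text{inflated}}^{(k)} - X_{\text{ref}})$,
re-inflating each iterate dynamically (smooth 10 ms pressure ramp, then a
damped stabilisation hold until the kinetic energy falls below 1e-4 of the
strain energy). With the bending-regularised wall the iteration contracts
geometrically; the default tolerance (max nodal round-trip distance 1e-3 mm)
is reached in about five iterations at physiological pressures. The update
is under-relaxed adaptively if a residual ever grows. Different pressures
and materials pulled back from the same reference give different
zero-pressure configurations, which is why the initial work of the IOP
(below) carries pressure information.

## Loading scenarios and time integration

Explicit central-difference (leapfrog) integration with lumped masses; the
stable time step is re-estimated every output increment from the current
tangent stiffness (numerical second derivatives of the wall energy, plus
bending and contact-penalty stiffness) with a 0.35 safety factor.
Mass-proportional damping is used only during pressurisation and the
stabilisation hold -- the loading phases run undamped, so the only energy
channels are elastic and kinetic.

* **Falling mass** (`run_falling_mass()`): a rigid 2.02 g cube, side
  1.5 mm, released 8 mm above the apex. Contact is a frictionless nodal
  penalty (30 MPa/mm over an area-equivalent circular footprint, keeping
  penetration below 2% of CCT); the contact-interface spring energy is
  booked as part of the eye's elastic energy. The run aborts with a
  diagnostic if penetration exceeds 10% of CCT.
* **Air puff** (`run_air_puff()`): a prescribed pressure field on the
  anterior corneal surface -- Gaussian footprint
  $\exp(-(r/r_f)^2)$, $r_f = 1.5$ mm, times a smooth $\sin^2$ pulse over
  30 ms. The peak stagnation pressure is the one free amplitude of the
  reduced-order jet; the default (80 mmHg) was fixed once so that the pulse
  applanates the cornea and the work curves cross over the whole clinical
  10--30 mmHg range, giving deformation amplitudes of 1--2 mm at
  physiological pressure. An optional coefficient attenuates the local
  pressure as the surface recedes (deformation-dependent jet pressure); it
  defaults to off.

## Work bookkeeping

Both work integrals act on the anterior corneal node set only (the surface
the device actually images) and along `y` only (axisymmetry cancels the
in-plane components ring-wise). Per output increment $j$ and node $i$,

$$W^j = \sum_i \tfrac12\big(F_i^j + F_i^{j-1}\big)\big(u_i^j-u_i^{j-1}\big),
\qquad F_i^j = P^j_i\,A^{(y)}_i(t_j),$$

accumulated trapezoidally, where $A^{(y)}_i$ is the *y-projected* nodal
area recomputed from the current coordinates (the projected areas telescope
exactly to the rim disc, so a uniform pressure on a rigidly translating
patch gives $P\,A\,d$ exactly). For the IOP the nodal pressure is the
uniform cavity pressure; for the puff it is the recorded per-node applied
pressure. The trapezoidal sums converge at $O(\Delta t^2)$ to the
continuous work integral, which the tests verify against fine-step oracles.

The "initial work of the IOP" is the plateau value of $W_{IOP}$ at the end
of the stabilisation hold (robust to the ramp shape). `find_intersection()`
locates the crossings of the internal and external work curves by linear
interpolation; during a puff there are two, and the first (inward phase) is
the primary one used by the estimator.

## Events

* `max_velocity_time()`: global maximum of the inward apex velocity after a
  3-sample moving average (ripple at the output-sampling scale -- contact
  ringing in simulations, measurement noise in device traces -- otherwise
  biases the discrete argmax), refined by a least-squares parabola whose
  support scales with the smoothing window.
* `first_applanation_time()`: the central 3 mm chord of the anterior
  profile is fit with an even quadratic; applanation is the first instant
  its curvature magnitude drops below 1 m⁻¹ (radius of curvature beyond
  1 m). The device's proprietary flatness criterion is not public; this
  convention mirrors descriptions of device logic in the literature.

## Calibration and the estimator

`run_sweep()` executes the sixteen-case design (five pressures at fixed
cornea; eight material variations and three thicknesses at 15 mmHg -- the
design varies the *corneal* constants, so the limbal band keeps its fixed
conventional constants throughout). On the pressure series
`calibrate_wiop()` fits two ordinary least-squares quadratics -- IOP versus
initial work, and initial work versus maximum-velocity time -- and composes
them *exactly* into the quartic pressure map; the composition identity
(`compose_wiop()`) is algebra, verified pointwise to 1e-12 against direct
two-step evaluation. R² is reported as $1 - SS_{res}/SS_{tot}$.

`estimate_wiop()` ships, as its default calibration, the published quartic
derived from full fluid--structure simulations of the device (constant term
10.95 mmHg at zero time), with validity interval 6.8--12.9 ms -- the span
of maximum-velocity times of the published pressure series, obtained by
inverting its own quadratics at 10 and 30 mmHg. Outside that interval the
estimate is flagged as extrapolated rather than refused. Over the fitted
interval the quartic is strictly increasing: a later work intersection
reflects a larger initial work and hence a higher pressure. The estimate
depends only on the timing of the velocity peak, never on its amplitude.

## Synthetic traces

`generate_trace()` produces device-style traces (140 samples over 30 ms)
with known ground truth: an inward sine lobe whose exact maximum sits at
`t_app + lag`, a zero crossing at highest concavity, an outward rebound
lobe, and additive Gaussian noise. The summit is sharpened by a stationary
Gaussian factor (defaults: sharpness 0.6, width 1.0 ms) because a perfectly
flat sine summit cannot be timed to one sample under realistic noise --
device traces show localised summits. The two archetypes differ only in
their parameter distributions (healthy: applanation 7.5 ± 0.4 ms, lag
uniform 1--3 ms, peak 0.16 ± 0.02 mm/ms; keratoconic-like: 6.5 ± 0.6 ms,
2--5 ms, 0.24 ± 0.03 mm/ms); they exercise batch behaviour and claim no
clinical realism. `generate_work_curves()` builds monotone work-curve pairs
with a single exact crossing for testing the intersection detector.

What passing tests on these fixtures show is that the *analysis* chain is
correct given its inputs; they cannot show that real Scheimpflug traces are
free of artefacts (whole-eye motion, imaging noise structure) that the
generator does not emulate.

## Problem sizes and numerical conventions

The package defaults are desk-scale by design: 40 meridian nodes at
resolution 1 (about 110 at resolution 2), output every 0.25 ms, and
adaptive substeps of 2--10 µs. A pressurisation takes about a second on one
CPU; a full zero-pressure recovery plus puff takes a few seconds; the
sixteen-case sweep runs in about a minute. Key tolerances: zero-pressure
round trip 1e-3 mm; equilibrium at kinetic/strain energy 1e-4; fibre
exponent guard $k_2(\bar I-1)^2 \le 80$ in the solver (700 in the
point-wise constitutive API) -- beyond it the run aborts as a material
instability rather than overflowing; element stretches outside
[0.3, 2.5] abort likewise.

## Known limitations

* The jet is a prescribed pressure field, not a resolved air domain: the
  spatio-temporal pressure profile is a convention, and the quantitative
  agreement of the work-curve intersection with the maximum-velocity time
  is approximate in the puff scenario (1--2 ms at these settings; in the
  falling-mass scenario, where the external energy is exact, the
  coincidence holds to one output increment).
* Axisymmetry excludes keratoconic (asymmetric) geometries and off-axis
  jets; the fibre architecture is smeared into the meridional/
  circumferential pair and carries no dispersion.
* The limbal and scleral constants are conventions (the design table prints
  only the corneal constants); the re-derived calibration therefore differs
  numerically from the published one and is exposed side by side with it
  rather than replacing it.
* No viscoelasticity or dissipation of any kind: the energy balance is
  purely elastic, which is what makes the work bookkeeping closed.
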