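---
title: "Posterior tibial slope and TKA knee mechanics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior tibial slope and TKA knee mechanics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question the package addresses

After total knee arthroplasty (TKA), the sagittal tilt of the tibial
component — the posterior tibial slope (PTS) — is one of the few alignment
parameters the surgeon can deliberately vary.  A larger slope is believed to
encourage femoral rollback, lengthen the quadriceps lever arm and ease deep
flexion, but its consequences for articular contact, ligament loading and
patellar tracking are hard to observe directly.  `kneeslope` implements a
desk-scale musculoskeletal analysis of this question: a parametric implanted
knee whose tibial component can be re-implanted virtually at any slope, and a
quasi-static concurrent solver that predicts, frame by frame through a
functional activity, the muscle activations, the secondary tibiofemoral and
patellofemoral kinematics, and every contact and soft-tissue load that follows
from them.  Sweeping the slope and rank-correlating the outcome metrics
against it yields the sensitivity analysis that is the package's end product.

# Model

## Geometry and frames

All computations live in the **tibial reference frame**: X anterior, Y
superior, Z lateral (a right knee), origin at the centroid of the inlay
superior rim projected onto the baseplate plane.  Contact moments are reported
about this origin, forces in body weight (BW, subject mass 95.6 kg by
default), moments in N m, lengths in mm.

The implant is parametric rather than a manufacturer CAD file: the femoral
condyles are torus patches (sagittal radius 30 mm, frontal 20 mm, centres 46
mm apart), the inlay carries two matching concave dishes whose radii are
slightly larger (32/22 mm) — the defining property of the highly congruent
fixed-bearing design class being modelled — and the patellar button is a
spherical dome (12 mm) riding in a trochlear groove (floor radius 32 mm from
the flexion axis, transverse radius 18 mm).  Congruency, not brand-specific
shape, is what governs how contact responds to slope, so it is the property
the generator preserves and validates.  A `surface_mesh` stores vertices,
faces, outward normals and areas; the resolution parameter (elements per
condyle width, default 12, minimum 8) controls every patch.

Virtual implantation (`apply_pts()`) rotates the inlay about the frame's Z
axis through the frame origin; positive slope tilts the posterior edge
inferiorly.  Rotating about the origin rather than about the posterior cortex
isolates the slope effect from an anterior-posterior translation of the
component; the absolute A-P contact positions therefore carry a constant
offset relative to any convention that rotates elsewhere, which cancels in
all within-sweep comparisons.

## Elastic-foundation contact

Articular contact uses an elastic foundation: the polyethylene is a bed of
independent springs of depth `h` on a rigid backing, so local pressure depends
only on local penetration.  Penetration at each inlay (or button) face
centroid is measured by casting a ray along the inward face normal and taking
the distance to the first opposing-surface intersection reached from inside
the opposing solid (a compiled Möller–Trumbore kernel with grid pruning).
Two pressure laws are available, selected in configuration:

* linear: `p = K d / h`
* logarithmic: `p = -K log(1 - d / h)`

with foundation modulus `K = E (1 - nu) / ((1 + nu)(1 - 2 nu))`.  The default
material is UHMWPE-like (`E = 463` MPa, `nu = 0.46`, `h = 6` mm, linear law).
The two laws agree to first order in `d/h`; at the penetrations the default
studies reach (well under 0.5 mm) the choice is immaterial, which is why it
is config-level rather than structural.  The sphere-on-plane closed form
`F = pi K R delta^2 / h` serves as the standing oracle for the mesh
implementation, with refinement convergence asserted in the tests.

Per-face pressures integrate to the total contact force, the contact moment
about the tibial origin, medial/lateral compartment axial forces (split at
Z = 0 exactly; a centroid on the boundary counts as medial), per-compartment
pressure-weighted centres of pressure (CoP), contact area (faces with
positive pressure) and mean pressure (axial force over area).

## Ligaments

Ten structures span the joint: sMCL, dMCL, LCL, POL, pCAP, PFL, ITB, mPFL,
lPFL and the patellar tendon (PT), each a bundle of 1–4 tension-only strands
with the Blankevoort piecewise law (quadratic toe up to twice the transition
strain `eps_l = 0.03`, linear beyond; continuous value and slope at the
junction).  The cruciates are absent by design: the modelled implant class is
cruciate-sacrificing.  Attachment sites are placed parametrically on the
synthetic geometry (collaterals at the epicondylar planes, posterior
structures behind the flexion axis, PT from the button's distal pole to the
tibial tuberosity); stiffnesses are literature-order defaults and explicitly
not ground truth — every acceptance-grade result in the package is either
invariant to them or a within-model comparison.

What ties the soft tissue to reality is the **calibration rule**: every
strand's slack length is set so that its strain at full extension equals the
reference strain (2%).  The full-extension pose is the as-built reference
(flexion 0, secondary coordinates zero, surfaces exactly touching), which is
an equilibrium of the uncalibrated, unloaded model, so the rule is applied
once, deterministically, with no inner iteration.  Calibration is per strand;
calibrating to the bundle mean instead would leave individual strands off the
reference strain, which the per-strand rule avoids.  Slack lengths are frozen
when the slope is swept — recalibrating at each alignment would erase exactly
the soft-tissue consequences under study.

## Muscles

Six knee-crossing actuators: lumped vasti and rectus femoris (inserting on
the patella, wrapping a cylinder coaxial with the flexion axis), medial and
lateral hamstrings, and the two gastrocnemius heads.  Paths are straight
segments plus a tangent-arc geodesic over an engaged wrap cylinder; tendon is
rigid and force is activation-proportional (`F = a Fmax`), keeping the
redundancy problem convex.  Moment arms are tendon excursions,
`-dL/dcoordinate`, by central finite difference with rotations in radians.

One modelling point deserves emphasis.  Because the patella's six
coordinates are expressed relative to the femoral component, a quadriceps
muscle running femur-to-patella has *zero* tendon excursion when flexion is
perturbed with the patella riding along — the extension torque reaches the
tibia only through the patellar tendon and articular contact.  The
redundancy problem therefore uses the excursion of the whole extensor
mechanism (muscle path plus patellar tendon) as the quadriceps moment arm.
This is exact in the frictionless-pulley limit and only affects the speed of
the outer fixed point, not the converged equilibrium, which is always closed
on the true generalized forces.

## Concurrent solver

Knee flexion is the prescribed primary coordinate; the remaining eleven
(tibiofemoral adduction, internal rotation and three translations; six
patellofemoral) are secondary and must be in mechanical equilibrium, while
the muscles must close the flexion-axis moment balance (muscle moments +
passive moments from contact and ligaments + external demand = 0) at minimal
effort, `min sum(a^2)` with `0 <= a <= 1`.  The squared-activation cost (not
a cubed variant, and with no contact-energy term) buys convexity and a
unique, reproducible optimum, at the known price that pure
effort-minimisation underestimates antagonist co-contraction; an optional
activation floor for the flexors exists for co-contraction studies and
defaults to zero.

With one equality constraint and box bounds, the effort-optimal activations
form a one-parameter water-filling family `a_m = clamp(lambda c_m)` in the
moment-per-activation coefficients `c_m`.  The default solver therefore
treats the multiplier as a twelfth unknown and solves the eleven generalized
forces plus the exact flexion balance as a single root problem per frame —
the concurrent formulation in the literal sense.  The root finder is a
damped Newton with forward-difference Jacobian, Broyden updates between
iterations, trust-region step caps (the contact stiffness is strongly
state-dependent), a nonmonotone line search and deterministic nudges (the
residual is only piecewise smooth: faces enter and leave contact, wraps
engage), a tolerance-scaled ridge so that slack directions — an unloaded
patella, a multiplier without authority — take bounded steps, and warm
starts from the previous frame.  When the extensor mechanism is slack (the
unloaded swing phase) the multiplier loses all authority over the flexion
balance and the augmented system degenerates; those frames fall back to the
classic alternating fixed point (redundancy problem, then equilibrium,
repeated), which is also available throughout via
`solver_control(method = "alternating")` and is cross-checked against the
concurrent path in the tests.  Tolerances: 0.5 N on force coordinates,
0.05 N m on moment coordinates, 0.05 N m on the flexion balance; the
alternating loop additionally ends when secondary coordinates move less than
1e-3 (mm or deg) and activations less than 1e-4.

The reduction is quasi-static: inertial terms are dropped and each frame is
an independent statics problem.  The simulated activities are slow to
moderate and every research question in scope is a between-alignment
comparison of the same frames, so transient dynamics would add cost without
touching the comparisons.  Equilibria are checked for guess-independence in
the tests (two distant starts agree to 0.01 mm/deg); this is a probe of the
congruent default geometry, not a uniqueness theorem.

## Synthetic activities

The generators produce the inputs the analysis assumes, standing in for
gait-laboratory data:

* **walking** (heel strike to heel strike, default 50 frames, 1.1 s): flexion
  5° baseline with a 13° stance peak at 15% cycle and a 55° swing peak at
  72%; axial load a double hump of 2.4/2.2 BW at 25%/75% of stance (stance
  fraction 0.62) and exactly zero in swing; flexion-moment and A-P shear
  bumps during stance.  Bumps are Gaussians re-anchored so the cycle starts
  exactly at baseline; the anchoring correction is itself a Gaussian pinned
  at the cycle start, so it does not distort the waveform away from it.
* **squat** (standing – deep flexion – standing, default 50 frames, 4.5 s):
  symmetric flexion 5°–90°–5°; axial load 0.5 BW at standing growing with
  the sine of the flexion excursion to 1.3 BW at the bottom (anchoring the
  standing frame exactly at baseline); extensor demand proportional to
  flexion excursion, 45 N m peak.

Loads are delivered as an intersegmental wrench on the femur at the tibial
frame — the declared abstraction of marker/ground-reaction-driven inverse
dynamics.  Amplitudes were chosen once so the default model's axial contact
peaks land in the physiologic 2–3 BW band for walking; they are configuration
values, not fitted quantities.  Five-trial variability is emulated by a seed
list.  What the generators deliberately do not contain: skin-marker artefact,
trial-to-trial waveform idiosyncrasy, EMG, or any subject's real load path.
Passing tests on these inputs demonstrates the mechanics of the model, not
agreement with any measured subject.

Noisy "reference traces" (simulated signal plus seeded i.i.d. Gaussian noise)
exercise the RMSE and peak-error machinery; with 10^4 frames the recovered
RMSE approaches the injected noise s.d., which the tests assert within 5%.

## The slope sweep and its statistics

`run_pts_sweep()` calibrates once at the baseline alignment (7° by default),
then simulates the identical activity at each slope from -5° to 19° in 2°
steps (±12° about baseline), extracts peaks (cycle maxima) and ranges
(max - min) of every outcome metric, and computes Spearman rank correlations
between slope and each metric.  Peaks are over the full cycle — phase-resolved
traces remain available per frame.  With 13 design points there is no
sampling distribution, so no p-values are attached to the coefficients.  A
constant metric has undefined rank correlation and is reported as missing,
never as zero.  Reported knee flexion subtracts the slope shift from the
implant flexion angle so that component reorientation is not read as a
kinematic change.

Two metric conventions matter for cross-alignment comparison.  First,
compartmental centres of pressure are compared at a fixed cycle point — the
late-stance axial-force peak — in addition to their cycle extrema: the
extremum of a slowly-varying CoP trace is sensitive to facet-level wiggle
(a few tenths of a millimetre at the default resolution), while the
fixed-point sample isolates the alignment effect cleanly.  Second, the
anterior-posterior shear metric is expressed as the peak anterior force
transmitted to the *tibial* component, the side on which instrumented
implants measure joint load; on the femur side the baseline anterior shear
and the slope-induced posterior rotation of the dish normal partially
cancel, which hides the monotone growth of the transmitted shear.

# What the defaults can and cannot show

The directional findings the default model reproduces — femoral equilibrium
and both compartments' centres of pressure moving posteriorly as slope
increases, and peak quadriceps force falling — follow from the congruent
geometry: tilting the dish moves its low point posteriorly, the femur settles
there, and the posterior shift lengthens the extensor mechanism's lever arm.
The quadriceps trend in particular is *model-emergent*: it depends on the
extensor-mechanism geometry, and alternative geometry defaults (e.g. a much
flatter inlay, or a patellar tendon anchored far posteriorly) could weaken or
reverse it.  It is asserted as a signed rank correlation on the default
configuration and documented here as such, not as a universal property of the
solver.

Known limitations, deliberately out of scope: bone geometry and resection
planning, friction/wear/lubrication, finite-element deformation,
ligament wrapping and viscoelasticity, cruciate ligaments,
activation dynamics and EMG-driven control, full-body inverse
kinematics/dynamics, and any in-vivo validation data.  Problem sizes in the
shipped tests and acceptance script (50-frame activities, 13-point sweeps,
12 elements per condyle width) are the package's default study conditions.

# Numerical choices

* Penetration by centroid ray casting along face normals, no nearest-point
  fallback: deterministic and directly checkable against closed forms;
  adequate for congruent surfaces where opposing normals are nearly
  antiparallel.
* Compartment tie-break: a face centroid exactly on Z = 0 is medial.
* Finite-difference steps 1e-4 (mm or rad) for Jacobians; moment arms use
  central differences with 1e-3 rad and are Richardson-checked in the tests.
* The Newton line search works on the tolerance-scaled max-residual; steps
  are capped at 1.5 mm / 0.25 rad per iteration.
* Cold starts nest the condyles analytically in the (rotated) dish and
  pre-engage both contacts by 0.05 mm so the first Jacobian sees contact
  stiffness; a cold frame additionally relaxes the secondary coordinates once
  before the first redundancy solve.
* Degenerate contact (no penetrating face) yields zero force, zero area and
  missing CoPs — flagged, not an error; penetration reaching the foundation
  depth is a hard error naming the faces, since the model is outside its
  validity there.
* All randomness (activity noise, reference traces) flows through explicit
  seeds; a sweep re-run with the same configuration and seeds writes
  byte-identical reports.

# A worked example

```{r example}
library(kneeslope)

model <- knee_model()            # parametric implant, default soft tissue
model <- calibrate_model(model)  # 2% strain at full extension, every strand

walking <- generate_walking_profile()
sim <- simulate_activity(model, walking)
summary(sim)

sweep <- run_pts_sweep(model, walking, sweep_alignments(7, 12, 2))
summary(sweep)
plot(sweep)
write_report(sweep, "pts_report")
```

The acceptance script (`scripts/acceptance.R`) re-runs the core computations
from scratch — calibration strain, sweep construction, the contact oracle,
the toy moment balance, the full walking sweep with its rank correlations,
and the statistics layer — and writes them as JSON for external comparison.
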