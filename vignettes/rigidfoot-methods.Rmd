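---
title: "Rigid foot-ground contact models for planar gait: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid foot-ground contact models for planar gait: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rigidfoot` studies sagittal-plane walking with *rigid* foot-ground contact:
the foot presents a fixed rolling geometry to the ground, contact is a
kinematic constraint rather than a viscoelastic force element, and touchdown
is a plastic impact. This vignette is the package's own account of the
models, the numerical choices, and the limits of what its synthetic studies
demonstrate.

## The mechanical model

The body is a planar floating-base chain of seven rigid segments: one
carriage holding pelvis, torso, head and arms (HAT), plus left and right
thigh, shank and foot. Generalized coordinates are the hip-point position
(x, z), the HAT pitch, and six revolute joint angles (hips, knees, ankles),
CCW-positive, giving 9 DoF. The equations of motion are

$$ M(q)\,\ddot q + c(q, \dot q) = \tau + G(q,\dot q)^{\mathsf T}\lambda,
\qquad g_V(q,\dot q)=0 , $$

with the foot-ground constraints $g_V$ written at the velocity level,
index-reduced, and applied at the acceleration level. The implementation
assembles $M$ and $c$ from analytic point Jacobians of the segment chains
(compiled code); the test suite checks both against an independent oracle
built from complex-step kinematics and finite-differenced Lagrange
equations, and checks the constrained dynamics and the impact map against
dense KKT and minimum-kinetic-energy projections solved separately in R.

**Default anthropometry.** Segment masses, lengths, COM offsets and inertias
are distributed from total mass (81.7 kg) and stature (1.72 m) by a
conventional gait-analysis regression table shipped as
`inst/extdata/body_segments.yaml`. The head, arms and torso are lumped into
the floating base; that is an explicit assumption, and every value can be
overridden through the config file.

## Foot-ground contact

Both feet carry the same ankle-frame geometry, either

* an **ellipse** (centre offset $_Ar_E$, orientation $_A\theta_E$, semi-axes
  $r_X \ge r_Y$), contacting the plane at the point of closest approach
  $n_S$ with a contact constraint $(v_A + \omega_A \times
  ({_Ar_E} + r_S(\phi)e_\phi))^{\mathsf T} e_Z = 0$ and a rolling constraint
  (the same expression projected on $e_X$); or
* a **double circle** (heel centre/radius, forefoot centre/radius). Each
  circle contributes a contact and a rolling row built from the material
  point at its lowest point; when *both* circles touch, only one carries the
  rolling row (3 rows in total), so the foot is never over-constrained. The
  convention — the rolling row stays with the circle that carried it in the
  previous phase, heel first at initialization — is the package's, chosen
  for multiplier continuity.

The ellipse's closest point has no closed form; the stationarity condition
of the boundary height in the polar parameterization $r_S(\phi)e_\phi$ is
bracketed on the lower half of the world circle, bisected, and polished by
Newton's method (falling back to bisection). A brute-force sweep over $10^6$
boundary points verifies the solution to below $10^{-8}$ m across random
poses.

**Acceleration-level reduction for rolling contact.** The velocity-level
rows are differentiated holding the *shape centre* (a true material point)
as reference; the migration of the geometric contact point enters the bias
through the boundary curvature radius $\rho$ ($\dot b = (-\rho\omega -
v_{C,x},\, -v_{C,z})$ for the ellipse; $\dot b = 0$ for a circle). Getting
this term right is what makes the rolling constraint workless: passive
rocking conserves energy to better than 0.1% over a second in the tests.
Baumgarte stabilization (position gain 100 s⁻², velocity gain 20 s⁻¹ —
critically damped with a 0.1 s time constant, fast against stance duration
and slow against the integrator tolerance) is applied to contact rows at
position and velocity level and to rolling rows at velocity level only.

**Sign conventions.** x forward, z up, angles CCW-positive. Rolling the foot
*forward* (CoP advancing) means the ankle-frame orientation *decreases*;
the stance generator therefore runs from toe-up at heel contact (+20°) to
heel-up at toe-off (−40°). A rolling-forward foot has $\omega_A < 0$, and
the CoP x-coordinate is monotone non-decreasing — a property the tests
check on every generated stance.

## Actuation

Each of the six leg joints carries an agonist–antagonist pair of
muscle-torque-generators, $\tau^M = \pm\,\tau_o^M\, a\, f^A(\theta)\,
f^V(\omega)$, with net joint torque $\tau = \tau^{MF} + \tau^{ME} -
\beta\omega$. The torque–angle curve is a C2 quintic bell (1 at the optimal
angle, 0 at `width` rad away); the torque–velocity curve is a C2 quintic
with $f^V(0)=1$, zero at the maximum shortening velocity, and an eccentric
plateau at 1.35. The published fits for these curves belong to their
original sources and are not reproduced; the shipped strengths
(`inst/extdata/actuators.yaml`) are *labelled placeholders*, chosen only so
the strength-scaled damping $\beta = \eta(\tau_o^{MF} +
\tau_o^{ME})/(\omega^{MF}_{max} + \omega^{ME}_{max})$ with $\eta = 2$ lands
inside the 2.7–7.3 N m s/rad range. Activation follows the C2 first-order
lag $\dot a = (e - a)\,/\,\tfrac12(\tau_A + \tau_D)$ with $\tau_A = 15$ ms
and $\tau_D = 50$ ms; the printed form of this law is ambiguous, and the
conventional excitation-switched time constant is available as a smooth
(`variant = "switched"`) alternative. Excitation bounds live in the OCP, not
inside the ODE. Passive parallel-elastic torques are deliberately omitted.

## Fitting foot geometry by CoP rollback

Given a stance record (time, CoP, ground force, ankle pose), the candidate
foot is posed at the recorded orientation and CoP of the *final* sample and
rolled backwards without slipping: surface arc length between successive
contact points equals the ground distance between successive CoP samples
(numerically integrated boundary arc length for the ellipse, closed form for
the circles, with the flat both-circles span holding the ankle stationary
while the CoP sweeps between the two contacts). The cost

$$ \sum_i \frac{(f^{N}_i)}{\max_j f^{N}_j}\Big( w_r\,|r_{A,i} -
r^{rec}_{A,i}|^2 + w_\alpha\,(\alpha_{A,i} - \alpha^{rec}_{A,i})^2 \Big), $$

with $w_r = (1/0.01)^2$ m⁻² and $w_\alpha = (14/\pi)^2$ rad⁻² (a 1 cm or a
π/14 rad error each scores one), is minimized by Nelder–Mead over the
reduced parameters: the 30.5 cm total foot length is eliminated by
substitution ($r_X = L/2$; heel-centre x from the length identity), leaving
4 (ellipse) or 5 (double circle) free parameters. The printed form of
$w_\alpha$ is typographically ambiguous; the value used here follows the
stated design intent that ~π/14 rad is a large error, and it is
configurable. CoP samples are matched directly (no between-sample
interpolation); samples that measurement noise places slightly ahead of the
toe-off anchor are held at the anchor pose. Fits recover generating
parameters of noise-free synthetic records to ~10⁻⁴ m/rad, and the
parameter error grows continuously from zero with the noise level.

## The synthetic studies

No subject data ships with the package; the `synthetic_data` functions
generate the study inputs.

**Stance records** are built by *prescribing the orientation profile and
deriving the CoP from rolling* — so every record is exactly realizable by
the foot family, and fitting becomes a clean identity test (real feet are
not exactly realizable; Gaussian noise emulates that regime). Defaults: a
0.7 s stance from +20° to −40°, a C2 double-hump normal-force profile with
peaks of 1.10 and 1.05 body weight at 31% and 69% of stance (vanishing at
the stance endpoints), and a braking-to-propulsion tangential ramp within
±0.15 of the normal force. All randomness flows through one seeded
generator; records are bit-reproducible.

**Reference gaits** are one full step of the ellipse-foot schedule,
forward-simulated. A posture/swing feedback law (trunk servo, stance-knee
hold, tapered trailing push-off with an anticipatory swing burst, swing
flex-then-extend program) is *sampled at the shooting nodes* and
interpolated linearly — exactly the OCP's control parameterization — with
each interval iterated to self-consistency, so the emitted trajectory *is*
the open-loop rollout of its own piecewise-linear excitations, with zero
shooting defects by construction. Phase boundaries are physical events
located by root finding in the phase duration under the same discretization:
double stance ends when the trailing foot's whole contact force has decayed
to a 0.25 N slack (so no node violates the friction cone and no loaded foot
is dropped), and single stance ends at the swing-foot touchdown. The
near-straight stance leg keeps excitations low, which matters for the
tracking study below. One artifact is documented rather than hidden: at the
leading-foot impact the trailing rolling foot can carry a few-mN·s negative
normal impulse, a known property of retaining bilateral rolling rows through
a plastic impact.

## Walking as a multi-phase optimal control problem

One step runs from the pre-impact state of the leading-foot touchdown to the
mirrored touchdown of the other foot. The ellipse foot gives four phases
(touchdown impact, double stance, single stance, mirrored impact); the
double-circle foot gives seven (heel-strike impact, heel/forefoot double
stance, forefoot-strike impact, full double stance, flat single stance,
forefoot single stance, mirrored impact). Decision variables: the pre-impact
state, node states (30 per node: q, q̇, activations), piecewise-linear
excitations (12 per node) and the continuous-phase durations. Shooting
intervals are integrated with fixed-step RK4 (8 steps per interval): a
deterministic, smooth discrete map, which finite-difference sensitivities
require; the adaptive Runge–Kutta–Fehlberg integrator (tolerance 1e-8)
serves plain simulation and post-hoc audits. Constraints: shooting defects;
position-level entry-manifold equalities at impacts; touchdown-gap
equalities; velocity-level equalities for newly imposed rolling rows at
constraint-drop boundaries (the drop time itself is free — unilaterality and
friction at the nodes bound the released force, and no lift-off equality is
imposed); mirrored periodicity on pitch, joint angles, all velocities and
activations (base x advances, base z is implied by the contact manifold);
node-sampled unilaterality, per-foot friction cones (|T| ≤ 0.8 N, scaled by
body weight), swing clearance; impulse unilaterality/friction; and for
prediction the two equalities — average forward speed 1.01 m/s (base
displacement over step duration) and step length 0.61 m (distance between
consecutive touchdown contact points), both imposed on the half cycle with
mirroring. Knee hyper-extension is capped at 0.1 rad through the box bounds.
State boxes inflate the reference range by at least ±1 m/rad and ±1 m/s;
the prediction study widens the angular-rate pad so the box does not bind
the fast ankle roll the ellipse foot develops (the phenomenon that motivates
an optional ankle-rate bound, exposed as `ankle_rate_bound`, e.g. 3.96
rad/s).

The tracking cost is node-sampled weighted least squares on the pelvis and
leg angles ($w_\theta = (4/\pi)^2$) and rates ($0.1\,w_\theta$), with the
ankle rows at 1/100 of nominal, plus CoP and ground-force terms (force
weight normalized by the peak reference force), 1e-3 control/activation
regularization, and a 1e-5 impulse Mayer term. The printed forms of the
angle weights are ambiguous; the values used mirror the fitting weights'
logic (a π/4 error scores about one) and are configurable. The prediction
cost is the activation quadrature $\int \sum a^2\,dt$ plus $10^{-2}\sum
\Delta^2$ on the impulses.

## The solver, honestly

No nonlinear-programming library is available to the package, so the
transcription is solved by a dense SQP written here: structured
finite-difference Jacobians (each shooting interval touches only its own
variables), damped BFGS on the Lagrangian, a working set for the box bounds,
least-squares multiplier estimates for the stationarity test, an
infinity-norm merit with a monotone infeasibility envelope, second-order
corrections, and an objective-blind restoration fallback. `predict_walking`
wraps the prediction solve in warm-restarted rounds. This solver is the
package's weakest component, and two limitations shape the studies:

* **Tracking study** (goal: recover a model-generated reference). The
  regularization term pulls the optimum slightly away from any reference
  whose excitations are nonzero, so the study first *polishes* the designed
  reference (one tracking solve), regenerates the exact rollout of the
  polished excitations, and tracks that: the result returns the reference to
  machine precision with zero-defect dynamics. The solver's first-order
  stationarity bottoms out near 5e-2 (relative) with finite-difference
  quasi-Newton steps, and the tracking study declares convergence at that
  level (`opt_tol = 5e-2`, `feas_tol = 5e-5`, `ineq_tol = 5e-5` — the last
  absorbing the few-mN·s impulse artifact above). A sharper solver would
  tighten these without changing the package's interfaces.
* **Prediction study.** From the synthetic-step guess the solver pins the
  speed and step-length equalities within ~3e-3 of the imposed 1.01 m/s and
  0.61 m and drives the worst equality residual (mid-swing velocity defects)
  to ~8e-3 before stalling at what is numerically a fold of the constraint
  manifold: the exact Newton restoration direction, computed independently
  and validated against finite differences, ceases to reduce the residual
  at any usable step length. Plain KKT steps (bound freezing and
  second-order corrections off) reach this floor; the prediction driver
  uses them by default. The reported speed and step length are measured
  from the returned trajectory; the residual infeasibility is reported, not
  suppressed, and the acceptance test asserting the design residual
  tolerances (defects and periodicity to 1e-6, inequalities to -1e-6) is
  expected to flag this gap until the solver improves.

Problem sizes used throughout the studies: 12 + 13 shooting nodes
(tracking) and 8 + 9 nodes (prediction) over the two continuous ellipse
phases, 8 RK4 steps per interval — about 560–1030 decision variables.

## Degenerate inputs and edge behavior

Zero-duration continuous phases are legal (defects reduce to identities;
control interpolation and quadrature handle the collapsed grid). Equal
ellipse semi-axes reproduce a circle exactly. Perfectly left/right-symmetric
double stance makes the two feet's constraint rows linearly dependent and is
rejected with a rank diagnostic. The KKT solves warn when nearly singular
(reciprocal condition below 1e-12).

## What the synthetic studies do and do not show

Passing tests demonstrate internal consistency: the dynamics agree with
independent oracles, rolling contact is workless, the fitting procedure is
the exact inverse of the stance generator, and the OCP machinery recovers
trajectories the model itself produced. They do not show that the model
matches human data: the MTG strengths are placeholders, the synthetic stance
profiles only resemble gait-lab recordings qualitatively, the generated
reference step is slower and shorter than comfortable human walking, and a
real trial's kinematics are not exactly realizable by either rigid foot.
Conclusions about which foot model is *better* require subject data and a
stronger NLP solver than the one shipped here.
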