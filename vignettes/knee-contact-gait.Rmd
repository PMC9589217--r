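---
title: "Concurrent musculoskeletal and finite-element knee contact analysis during gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent musculoskeletal and finite-element knee contact analysis during gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`kneegait` couples a right-lower-limb musculoskeletal analysis with a
deformable finite-element model of the tibiofemoral joint, at desk scale, to
study how medial meniscus radial tears and total medial meniscectomy change
knee loading during the stance phase of gait. The pipeline per stance time
point is

1. **Inverse kinematics** — primary joint angles (pelvis 6-DOF, hip
   flexion/adduction/rotation, knee flexion, ankle dorsiflexion) fitted to
   marker trajectories by per-frame damped Gauss–Newton least squares.
2. **Inverse dynamics** — bottom-up Newton–Euler recursion (foot → shank →
   thigh) under the measured ground reaction force, giving net joint moments
   and the tibiofemoral intersegmental load.
3. **Static optimization** — twenty Hill-type muscle units resolve the
   moment demands by minimizing the sum of cubed activations,
   `C = min Σ s³`, subject to moment equilibrium at the hip (three
   components), knee flexion–extension and ankle dorsi/plantarflexion, with
   `0 ≤ s ≤ 1`.
4. **Contact solve** — the five knee secondary degrees of freedom (three
   tibiofemoral translations, varus–valgus and internal–external rotation)
   are driven to quasi-static equilibrium of the deformable contact plus
   ligament wrench against the applied tibiofemoral load.
5. **Feedback** — the converged secondary kinematics reposition the tibia in
   the musculoskeletal model, updating muscle lengths, moment arms and the
   knee moment; steps 2–4 repeat until the knee flexion–extension moment is
   stable (default tolerance 0.5 N·m, at most 10 iterations).

The stance phase is evaluated at 16 evenly distributed time points
(0, 6.67, …, 100 % stance). The experiment matrix runs eleven knee variants
under identical marker and force-plate inputs: one intact knee, radial tears
of the medial meniscus at the anterior horn, midbody and posterior horn with
33 %, 50 % and 83 % of the width torn, and a total medial meniscectomy.

```{r}
library(kneegait)
cfg <- simulation_config()
mx <- run_experiment_matrix(cfg)
report(mx, "results")
```

## The synthetic data

No subject data ship with the package; everything is generated.

**Knee geometry** (`build_knee_geometry()`) is a parametric stand-in for
segmented imaging data: femoral condyles as bi-radius circular caps
(sagittal 35 mm, frontal 24 mm, C¹-continued beyond 85 % of each radius),
a mildly dished tibial plateau with bonded isotropic cartilage layers
(E = 5 MPa, ν = 0.46, 2 mm), and C-shaped swept-wedge menisci (annulus
10–21 mm, wedge 0.8–7 mm tall, 300° extent partitioned 90/120/90° into
anterior horn, midbody and posterior horn). Menisci are transversely
isotropic with the stiff axis circumferential (140 MPa circumferential,
20 MPa radial/axial, in/out-of-plane Poisson ratios 0.2/0.3); each element
carries a local frame whose circumferential vector is tangent to the annulus
centroid ring. Radial tears are created by deleting the innermost
`round(width_fraction · n_rad)` radial element rings of a one-element-wide
circumferential slot, through the full thickness; the radially adjacent
surviving elements are tagged as the tear tip. Because torn meshes are made
by deletion, matched-location comparisons against the intact knee are exact
element-index lookups.

Four meniscal horn attachments are linear spring sets with per-spring
stiffness `k = E·a / (n·l)` (E = 600 MPa, a the horn face area, l each
spring's length), so the parallel assembly reproduces the axial stiffness of
a uniform rod; the anterior transverse ligament is a 12.5 N/mm spring set
joining the anterior horns. Ligaments (ACL, PCL, MCL, PMC, LCL, ALS, OPL as
23 bundle elements) follow the tension-only piecewise law — quadratic toe
region up to twice the reference strain `ε_l = 0.03`, linear beyond — with
the published stiffness table validated at load time. Slack lengths are
calibrated so each bundle carries its configured reference strain (default
zero) at the full-extension reference pose.

**Gait trials** (`generate_gait_trial()`) drive the linkage with template
joint-angle curves (natural splines through control points shipped as YAML)
and emit marker trajectories at 100 Hz by forward kinematics plus seeded
Gaussian noise, and a double-hump vertical ground reaction force at 1000 Hz
(peaks ≈ 1.10/1.12 body weight at ≈ 25 % and 74 % stance) with
anterior–posterior and mediolateral components and a heel-to-toe centre of
pressure. The default subject is 80 kg and 1.75 m. The template was
calibrated once against published gait envelopes — braking force peaking
near 15 % stance and decaying by 30 %, late-stance knee flexion reaching
13°/30° at 75/90 % stance — so that the inverse-dynamics moments stay in
physiological bands (knee ≈ 0.5–0.8 N·m/kg) and the moment demands lie
inside the 20-muscle set's feasible cone.

**What the generator does not emulate**: soft-tissue artefact (noise is
white), bilateral mechanics, subject geometry variability, segmentation
error, and the real menisci's non-uniform cross-sections. Passing tests
demonstrate internal consistency of the method at desk scale, not clinical
accuracy for any real knee.

## The muscle set

The twenty units follow the study list (gluteus maximus as three units,
iliopsoas, pectineus, rectus femoris, three vasti, semimembranosus,
semitendinosus, biceps femoris long and short heads, two gastrocnemius
heads, soleus, tibialis anterior and posterior, extensor hallucis and
digitorum longus). Parameters are literature-scale and fully editable YAML.
Because the list contains no dedicated hip abductor or internal rotator —
yet three-component hip moment equilibrium must hold — the fixture places
the upper gluteus maximus unit on the lateral iliac crest with an iliotibial
insertion (abduction capacity), gives iliopsoas a via point anterior to the
femoral head (flexion with near-neutral axial rotation) and semitendinosus a
medial-thigh via point (small internal rotation). Biarticular units are
calibrated to sit below optimal fiber length at the upright reference pose
(`ref_lnorm` 0.85–0.95), which keeps passive hamstring forces physiologic at
heel strike. The tendon is rigid and there is no force–velocity term:
muscle forces are resolved per time point, so only the force–length
properties matter (Gaussian active curve of width 0.45; exponential passive
curve reaching 1 at 60 % passive strain).

Moment arms use the tendon-excursion method (`r = −∂L/∂q`, central
difference); path lengths run through via points with tangent–arc–tangent
cylinder wrapping where a straight segment would penetrate the assigned
cylinder (the quadriceps wrap a 25 mm condylar cylinder at deep flexion,
standing in for the patellar mechanism). Quadriceps force reaches the tibia
through this effective patellar-tendon line; patellofemoral cartilage stress
is deliberately out of scope.

## The static optimization

The cubic program `min Σ s³` subject to `A s = b`, `0 ≤ s ≤ 1` is solved by
a primal–dual interior-point method (separate primal/dual step lengths,
adaptive centering while primal-infeasible) followed by an active-set Newton
polish that clamps bound-active activations exactly and verifies multiplier
signs — so degenerate optima such as the all-zero solution at zero demand
are recovered exactly, and KKT residuals reach machine precision on
well-posed problems. Demands that exceed muscle capacity are reported as
infeasible together with the bounded least-squares moment fit; nothing is
silently relaxed.

## The contact model

The deformable bodies are the two menisci — assembled as one coupled linear
system including horn springs and the transverse ligament — and the two
tibial cartilage layers with bonded bases. All contact is node-to-rigid
surface penalty:

* meniscus and cartilage top nodes against the femoral condyle cap, whose
  bone-mounted cartilage enters as an elastic-foundation compliance in
  series with the numerical penalty (default 50 N/mm³);
* meniscus bottom nodes against the cartilage-backed tibial plateau plane.

The condyle cap has a circular sagittal profile, so knee flexion leaves the
contact surface invariant; the femur pose in the contact solve is therefore
exactly the five secondary DOFs (about the condylar axis point), while
flexion rotates the ligament attachments. Friction is regularized Coulomb
with μ = 0.04 and a 0.2 mm slip tolerance. Hexahedra use full 2×2×2 Gauss
integration; the near-incompressible cartilage uses the mean-dilatation
(B-bar) volumetric treatment. The unspecified out-of-plane shear modulus of
the transversely isotropic meniscus defaults to 10 MPa (in-plane
`E_trans/(2(1+ν_in))` ≈ 8.3 MPa); the assembled tensor is checked positive
definite at load time.

### Numerical choices

* **Inner solve.** Per femur pose, each body is solved in two deterministic
  passes: the frictionless normal-penalty problem by full Newton steps with
  residual backtracking, then a re-solve with friction frozen from the
  frictionless field. The result is a pure function of the pose — warm
  starts only accelerate — which keeps the outer residual smooth. The
  penalty force has a quadratic transition over the first 0.02 mm of
  penetration so grazing contact does not chatter, and the Jacobian carries
  the gap-gradient magnitude of the sloped surfaces. Factorizations reuse a
  cached symbolic Cholesky analysis (contact only touches nodal diagonal
  blocks already in the stiffness pattern).
* **Outer solve.** Newton on the five secondary DOFs with an analytic
  Jacobian assembled from adjoint solves of each body system (including the
  friction–normal force coupling) plus a finite-difference ligament block.
  Cold starts ramp the applied wrench with adaptive increments (growing on
  success, bisecting on failure); warm starts attempt the full load directly
  and fall back to the ramp. Equilibrium tolerance is 1.5 % of the applied
  load with absolute floors of 5 N and 250 N·mm — chosen at the solver's
  noise floor; the global-equilibrium invariant is asserted at exactly this
  tolerance.
* **Stress recovery** uses the volume-averaged strain–displacement operator
  per element (consistent with the stiffness integration); maximum shear is
  `(σ₁−σ₃)/2` from the principal stresses, and the hoop stress is the
  projection `σ_cc = cᵀσc` onto the local circumferential vector, tension
  positive. The full tensor is retained so alternative scalars can be
  derived; figures and summaries use maximum shear as the "shear stress"
  scalar.

### Load partition

Per contact pair the converged tractions are summed; the medial load-share
ratio is `|F(femur→medial meniscus)| / (|F(→medial meniscus)| +
|F(→medial tibial cartilage direct)|)`. A zero medial total reports the
ratio as missing, never as zero. After meniscectomy the medial meniscus
force is identically zero and the cartilage share is exactly one.

## Problem sizes and performance

The standard case uses a deliberately coarse mesh chosen for single-CPU R:
menisci 12×6×1 elements per side, tibial cartilage 8×8×1, plus the
bone-mounted layers and rigid shells (≈ 600 hexahedra and 700 triangles,
≈ 2100 deformable degrees of freedom in the largest system). At this size
one stance run converges at all 16 points in under a minute and the full
11-variant matrix in a few minutes. The single-hexahedron material tests,
the sphere-on-layer benchmark and the refinement smoke test (one step of
mesh refinement changes the standard-case total contact force by < 5 %)
guard the accuracy of this choice.

## Design decisions where the problem was open

* The tear slot spans exactly one circumferential element column; tear
  "thickness" is not otherwise defined, and deletion from the intact mesh
  keeps intact/torn comparisons index-exact.
* The horn-spring constant is read as the axial-rod form `E·a/(n·l)` on
  dimensional grounds (MPa·mm²/mm → N/mm) and because the parallel assembly
  then has the rod stiffness `E·a/l` independent of n.
* The ligament law's two branches need not meet at the transition strain for
  arbitrary published constants; the law is implemented literally and
  `ligament_force_jump()` reports the per-bundle discontinuity instead of
  smoothing it.
* Knee equilibrium in the static optimization is enforced on
  flexion–extension only; the remaining knee components are balanced by the
  contact/ligament solve, mirroring the split in which secondary DOFs are
  determined entirely by joint mechanics.
* One coupled program enforces hip, knee and ankle moment constraints
  simultaneously (the alternative of per-joint programs would decouple
  biarticular muscles).
* The outer concurrent loop iterates per time point with warm starts from
  the previous point (and, across variants, from the intact solution), not
  jointly over the whole trajectory.
* A quasi-static implicit solve replaces explicit dynamic relaxation: the
  analysis lives at 16 discrete stance points, so statics is the faithful
  desk-scale contract.

## Known limitations

* The synthetic stand-in reproduces directions, not magnitudes: on the
  standard case the intact medial meniscus carries ≈ 0.5 of the medial
  compartment load on stance average, meniscectomy roughly doubles the
  direct cartilage force, and wide midbody tears multiply the tear-tip
  shear severalfold — the qualitative pattern of the subject-specific
  study, at different absolute values.
* Ligaments are straight one-dimensional elements without wrapping or
  contact with the menisci.
* Cartilage is single-phase linear elastic; no biphasic or fibril-reinforced
  behavior, and no tissue-property changes after tearing.
* The patellofemoral joint is a force-transmission device only; its
  cartilage mechanics are not reported.
* Lumbar and upper-body degrees of freedom are excluded; the linkage is the
  right lower limb.
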