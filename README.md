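# kneegait

Desk-scale concurrent musculoskeletal and finite-element analysis of the
knee during the stance phase of gait, built to study how **medial meniscus
radial tears** and **total medial meniscectomy** change meniscal stress and
tibial cartilage loading.

Radial tears cut the circumferential collagen fibers that let the meniscus
convert joint compression into hoop tension, and long tears are often
treated by meniscectomy — which removes the meniscal load-sharing path
entirely. `kneegait` quantifies both effects within one mechanically
consistent model of a single gait trial: the same marker trajectories and
ground reaction force drive an intact knee, nine tear variants (anterior
horn / midbody / posterior horn × 33 / 50 / 83 % of the meniscal width) and
a meniscectomized knee, and the package reports meniscal shear and hoop
stress fields, tear-tip stress series, and the partition of the medial
compartment load between meniscus and cartilage.

## The model

Per stance time point *t* (16 points, 0–100 % stance):

1. **Inverse kinematics.** Primary angles θ (pelvis 6-DOF, hip 3-DOF, knee
   flexion, ankle dorsiflexion) from marker least squares.
2. **Inverse dynamics.** Newton–Euler recursion under the measured ground
   reaction force gives net joint moments *M<sub>j</sub>* and the
   tibiofemoral intersegmental load.
3. **Static optimization.** Twenty Hill-type units resolve
   *M<sub>j</sub>(θ<sub>j</sub>, e<sub>s</sub>) = Σ<sub>m</sub>
   r<sub>jm</sub>(θ<sub>j</sub>, e<sub>s</sub>) · f<sub>jm</sub>(s<sub>m</sub>)*
   by minimizing *C = Σ<sub>m</sub> s<sub>m</sub>³* with
   *0 ≤ s<sub>m</sub> ≤ 1* (interior-point solve with an active-set polish).
4. **Deformable contact.** The five knee secondary DOFs *e<sub>s</sub>*
   (three tibiofemoral translations, varus–valgus, internal–external
   rotation) are driven to quasi-static equilibrium of the penalty-contact +
   ligament wrench against the applied load. Menisci are transversely
   isotropic hexahedral bodies (140 MPa circumferential / 20 MPa
   transverse), cartilage isotropic (5 MPa, ν = 0.46), friction μ = 0.04,
   ligaments tension-only piecewise (quadratic toe to 2ε<sub>ℓ</sub>,
   ε<sub>ℓ</sub> = 0.03, then linear), horn attachments as
   *k = E·a/(n·l)* spring sets.
5. **Feedback.** *e<sub>s</sub>* re-enters the musculoskeletal stage
   (muscle lengths, moment arms, knee moment) and 2–4 repeat until the knee
   flexion moment is stable (0.5 N·m).

All inputs are synthetic and generated by the package: a parametric knee
(bi-radius condyle caps, dished tibial plateau, C-shaped swept-wedge menisci
whose tears are made by element deletion) and a template-driven gait trial
(100 Hz markers by forward kinematics, 1000 Hz double-hump ground reaction
force, 80 kg / 1.75 m subject). See the vignette
(`vignettes/knee-contact-gait.Rmd`) for the full model description, the
numerical choices and the known limitations.

## Worked example

```r
library(kneegait)

cfg <- simulation_config()            # 16 stance points, 11-variant matrix
mx  <- run_experiment_matrix(cfg)     # a few minutes on one CPU
print(mx)
report(mx, "results")                 # CSV summaries + VTK stress fields
```

On the standard synthetic case this prints (abridged):

```
Experiment matrix: 11 variants (0 failed); GRF peaks at grid points 5 and 12
  peak medial cartilage force change vs intact (%):
    anterior_horn_33      +3.1
    midbody_50            +6.5
    midbody_83           +13.0
    posterior_horn_83     +9.1
    meniscectomy         +87.4
```

Reading these numbers: the two GRF peaks (grid points 5 and 12, i.e. ≈ 27 %
and ≈ 73 % stance) are maximum weight acceptance and push-off. Radial tears
barely change the direct femur→cartilage contact force (+3 to +13 % even at
83 % width) because the remaining meniscal rim still carries hoop tension;
total meniscectomy removes that path and raises the direct cartilage force
by ~87 % (1.36 → 2.64 body weight at weight acceptance) and the medial peak
contact pressure by ~49 %. The tear-tip maximum shear stress of the 83 %
midbody tear reaches several times the matched-location intact value at the
GRF peaks — the stress-concentration mechanism that makes wide midbody
tears prone to complete rupture — while the medial meniscal share of the
compartment load falls from ≈ 0.50 (intact, stance average) to 0 after
meniscectomy.

Single variants run via `run_stance(build_knee_geometry(), cfg)`; per-tier
results (secondary kinematics, activations, contact partitions, stress
fields) are in the returned `stance_solution`.

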