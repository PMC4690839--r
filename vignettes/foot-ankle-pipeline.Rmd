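---
title: "Patient-specific foot and ankle modelling: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific foot and ankle modelling: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling decisions behind `mskfoot`: the
rigid-body model and its conventions, the patient-specific assembly chain,
the simulation stack, the sensitivity protocols, the synthetic-patient
generator that stands in for clinical data, and the numerical choices that
make the whole pipeline reproducible. It is the place to look when you need
to know *why* a default is what it is.

## The rigid-body model

The template is a single (right) lower limb with a three-segment foot:
pelvis, femur, shank, talus, hindfoot (calcaneus), forefoot (metatarsals)
and toes. Joints form a tree rooted at the ground: a 6-DoF pelvis
residual joint, a 3-DoF hip, a 1-DoF knee hinge, a 3-DoF ankle
(flexion/extension, inversion/eversion, internal/external rotation), a
zero-DoF weld carrying the talus on the hindfoot, a 3-DoF
hindfoot–forefoot joint and a 1-DoF metatarsophalangeal hinge — seventeen
coordinates in all.

Conventions, applied uniformly:

* Segment frames are right-handed, **X anterior, Y up, Z lateral** (right
  side) in the reference pose; all joint orientations are identity there,
  so world axes and segment axes coincide at reference.
* Lengths in metres, angles in radians, forces in newtons internally;
  marker files in millimetres are converted on read; the command line
  reports degrees and millimetres where conventional.
* Rotational coordinates are right-handed about their axis. A consequence
  worth knowing: about +Z the knee coordinate is *extension-positive*
  (knee flexion during gait is a negative angle) and ankle dorsiflexion is
  positive. Tendon-excursion moment arms are reported as
  $r_{ij} = -\partial L_i/\partial q_j$, so a plantarflexor has a negative
  arm about the ankle flexion coordinate.
* Muscle paths are via-point polylines. Wrapping surfaces are not
  modelled: the sensitivity protocol perturbs path points, which polylines
  support directly, and no wrapping geometry is published for the foot at
  the fidelity this pipeline targets. The cost is that broad-wrap muscles
  (deep hip rotators, peroneals around the malleolus) need via points
  placed to give literature-plausible moment arms — which is how the
  template was built (for example, the gastrocnemius heads arise from the
  posterior femoral condyles so they retain a knee-flexion arm, and the
  anterior gluteal fibres are routed low and anterior so their
  internal-rotation arm survives hip extension).
* Muscles are ideal force generators, $f_i = a_i F_{\max,i}$. Whether
  force–length/velocity scaling should modulate $F_{\max}$ during gait is
  a modelling choice the source data cannot arbitrate; the ideal generator
  is the reproducible default.
* Maximum isometric forces, segment masses, centres of mass and inertia
  tensors are **literature-plausible placeholders** shipped as
  configuration. They are not measured values and are deliberately easy to
  override (`default_template_config()` returns a plain list; models
  serialize to JSON).
* Seven ankle/foot ligament records (three lateral, three deltoid bands,
  the plantar fascia) are carried as inert geometry: their mechanical
  properties are too uncertain to include in simulation, and every shipped
  configuration keeps them inactive.
* The knee is a pure hinge by default. A polynomial coupling hook
  (`make_polynomial_coupling()`) accepts user-supplied regression
  coefficients for derived tibiofemoral translations/rotations; none ship
  because no coefficient set is packaged with the source models.

## Patient-specific assembly

`assemble_patient_model()` runs, in order, with every stage also callable
standalone and every transform/residual logged:

1. **Static averaging** — each marker's position in the standing trial is
   averaged over the frames where it is visible (markers visible in fewer
   than half the frames are rejected by name).
2. **Scaling** — pelvis depth (mid-ASIS to mid-PSIS), height (mean
   ASIS/PSIS point to mid greater trochanters) and width (right to left
   ASIS/PSIS midpoints); femur (greater trochanter to mid femoral
   epicondyles); shank (mid epicondyles to mid malleoli). The pelvis
   scales anisotropically with depth on its anterior axis, height
   vertical, width lateral — the dimension-to-axis assignment the
   dimension names imply. Femur and shank scale isotropically. Segment
   masses by default preserve the template's mass proportions at the
   patient's body mass (the patient's total mass is known, segment masses
   are not); a cubic volume-ratio mode is available.
3. **Foot–MRI registration** — Horn registration of the averaged static
   foot markers (including both malleoli) onto the six radio-opaque MRI
   marker replicas. This assumes the foot is rigid between the scan and
   standing; the residual of this stage is the measured cost of that
   assumption and is always logged.
4. **Per-segment landmark registration** — for shank, hindfoot, talus,
   forefoot and toes, a Horn transform from the generic landmarks to the
   patient's virtually palpated landmarks carries the generic muscle
   attachment and via points onto the patient's bones. Rigid, per segment:
   a deliberately conservative estimate (the clinical workflow refines
   these points against the muscle-path MRI by hand, a step outside this
   package).
5. **Cylinder ankle axis** — nonlinear least-squares cylinder fit to the
   talar dome cloud; the ankle centre is the midpoint of the fitted axial
   extent (the only well-defined centre of a finite patch) and the flexion
   axis is the cylinder axis, its sign disambiguated to point lateral by
   the malleolar medial-to-lateral direction. The shank frame recipe then
   re-uses the marker-based construction with the cylinder's axis
   endpoints in place of the malleoli. The foot subtree is re-anchored in
   this frame; world-space geometry is preserved exactly.
6. **Leg and pelvis registrations** — static leg markers onto the MRI
   malleoli plus the femoral condyles palpated in the scaled generic
   geometry (the femur is carried into MRI space with the shank's
   transform, knee at the reference angle); static pelvis markers onto the
   scaled generic ASIS/PSIS points.
7. **Femur rotation** — the femur's geometry is rotated about the knee
   flexion axis until the palpated greater trochanter is closest to the
   greater-trochanter gait marker (bounded Brent on a 1-degree grid
   bracket, tolerance 1e-10; degenerate when the trochanter lies on the
   axis).

A deliberately spartan note on the left side: the model is a single limb,
but pelvis-height scaling needs both greater trochanters, so a left-GT
marker rides on the pelvis segment. It participates in scaling distances
only.

## Simulation

`run_pipeline()` windows the trial to stance (vertical force above a 20 N
threshold — a conventional force-plate noise floor — taking the longest
supra-threshold run so noise spikes cannot truncate stance) and runs:

* **Inverse kinematics.** Per frame, Levenberg–Marquardt over the unlocked
  coordinates minimizing the weighted squared marker distances
  (uniform weights by default; the source protocols do not publish
  weights), warm-started from the previous frame. Non-converged frames
  carry the previous solution and are flagged.
* **GRF assignment.** 1SEG applies the plate wrench to the hindfoot
  throughout. 2SEG switches it entirely to the toes at the first frame
  where the centre of pressure passes the metatarsophalangeal axis along
  the forefoot's anterior direction; the switch is latched because a
  single crossing event is the modelled phenomenon and COP noise near the
  axis must not chatter.
* **Inverse dynamics.** Quasi-static by default: each applied wrench
  (ground reaction, segment weights) is projected onto every coordinate's
  instantaneous axis; inertial terms are dropped. The `full` mode adds
  inertial wrenches from centrally differenced segment kinematics; on the
  package's synthetic gait the two agree at the ankle to within a few
  percent, which is why quasi-static is the default (and matches the
  free-body reasoning used to sanity-check ankle loads).
* **Static optimization.** The constraint set is hip (3), knee, ankle
  flexion, ankle inversion and MTP flexion; the pelvis residuals are
  excluded (ground-referenced free body), and the hindfoot/forefoot
  coordinates and ankle internal/external rotation are locked — the plate
  data cannot distribute load across foot segments, and the ankle's
  passive structures are assumed to carry the internal/external rotation
  moment. The QP (diagonal Hessian, box bounds, equality constraints) is
  solved by a primal active-set method that always carries reserve
  variables internally so a feasible start exists; in `reserves = "off"`
  mode the reserve penalty is large (1e6) and the solution is then
  *polished* to an exact equality-constrained optimum on the final active
  set, so reported solutions satisfy every moment constraint to machine
  precision or the frame is declared infeasible with the violated
  coordinate named. Reserve actuators, when enabled, use a quadratic
  penalty with normalizing torque 1 N·m and weight 1000. `"auto"` retries
  a whole trial with reserves after any infeasible frame.
* **Joint reaction.** The ankle JRF on the foot is the intersegmental
  force minus the summed pulls of the ankle-crossing muscles along their
  joint-spanning strands, expressed in the chosen ankle frame and
  normalized by body weight. Its magnitude is frame-invariant; frame
  choice affects the simulation through the changed joint centre and
  constraint axes, not through the final projection.

## Sensitivity protocols

* **Muscle points.** Every point immediately on either side of the ankle
  for the ten relevant structures (the shared Achilles insertion of the
  triceps surae, and the tibialis anterior/posterior, peroneus
  longus/brevis/tertius, and long flexors/extensors of hallux and digits)
  is displaced 5 mm along each hindfoot-frame axis, both directions, one
  at a time — the direction convention is unspecified in the clinical
  protocol, so both signs are reported separately. Because muscle geometry
  does not enter kinematics or inverse dynamics, perturbation reruns reuse
  the baseline kinematics and re-solve only the affected moment-arm rows,
  the optimization and the reaction — this exactness is tested against a
  full rerun. Percent change is computed on the resultant JRF, stance is
  resampled to 101 points (0–100%) before averaging across trials, and
  the report filter keeps structures whose |mean change| reaches 0.5% in
  any perturbation.
* **Segment assumption.** The 2SEG − 1SEG difference of the mean JRF
  curve, with the peak difference expressed as a percentage of the peak
  JRF.
* **Ankle frame.** The cylinder-based frame versus the malleolar-marker
  frame, rebuilt from the model's own markers; runs that are infeasible
  without reserves are retried with reserves and flagged, and the scalar
  frame difference (rotation angle, origin offset) is reported alongside
  the JRF difference curve.

## The synthetic patient

`make_synthetic_patient()` and `make_walking_trial()` generate every input
the pipeline needs with known ground truth. Design choices, fixed once:

* The patient is the adult template scaled uniformly to 0.83 stature with
  51.6 kg mass and 1.45 m height — the mid-range of a 9–16-year-old
  cohort. Because the package maps the *unscaled* generic foot onto this
  child-sized anatomy rigidly (as the clinical workflow does before its
  manual refinement), the foot registration residuals of a few millimetres
  are a faithful feature, not a bug.
* The talar dome cloud is sampled from the known cylinder (radius = scaled
  template dome radius, 80° arc) with random angular positions on a
  regular axial grid spanning the full extent, so the patch determines the
  axial midpoint — and hence the joint centre — exactly; this is what
  makes the undeformed round trip an identity to 1e-9 m.
* The malleolar markers are placed with roughly 25° external torsion and
  an inter-malleolar midpoint about 16 mm lateral and inferior of the dome
  centre — a deliberately exaggerated juvenile hindfoot in which the
  marker-based ankle frame differs substantially from the articular axis.
  This construction is what makes the frame-definition experiment
  informative: under the marker frame, the Achilles' moment about the
  shifted inversion axis exceeds evertor capacity at push-off and the
  optimization needs reserve actuators there, while the image-based frame
  never does.
* Walking: 100 Hz markers, 1 kHz plate, 0.7 s stance with 0.2 s unloaded
  padding; joint-angle trajectories are natural splines through plausible
  control points (ankle −18°…+10°), and the pelvis advances ~0.5 m over
  the planted foot so the ground-reaction line stays near the knee and hip
  as it does in real stance. The vertical force is a double hump of 1.1
  and 1.2 body weight around a 0.8 BW valley; the centre of pressure runs
  heel to toe and crosses the MTP axis at 70% stance by construction; a
  small vertical free moment (3 N·m peak) is included.
* Everything is seed-deterministic and returns its generating values, so
  parameter-recovery tests (cylinder radius, per-segment transforms,
  inverse-kinematics angles, the COP crossing frame) compare against
  exact truth.

What the generator does *not* emulate — and hence what green tests do not
establish about clinical data: soft-tissue artefact (markers ride rigidly
on segments), marker gaps, non-rigid inter-bone deformation between MRI
and standing, force-plate coordinate misalignment (the lab-to-model
rotation is an explicit configuration, never guessed), and pathology
beyond the geometric exaggeration above. Oracle recovery at 1e-6 rad says
the estimators are correct, not that clinical inputs are this clean.

## Numerical choices

* Horn registration is the closed-form quaternion solution; degeneracy is
  declared when the smallest singular value of the cross-covariance falls
  below 1e-10 of the largest. The unit-quaternion construction cannot
  return a reflection.
* One geometric subtlety of the shank-frame recipe: the transverse axis is
  orthonormalized against the vertical axis, so a purely frontal-plane
  tilt of the dome axis (with coincident origins) does not change the
  frame at all — only transverse-plane rotation and origin offsets carry
  through. In the assembled pipeline the image/marker frame difference
  arises from exactly those two ingredients.
* Cylinder fitting parametrizes the axis as a perturbation of the best
  principal-component initialization (each principal direction is tried
  with an algebraic circle fit and the best kept), with the axis point
  constrained to the plane through the centroid — removing the gauge
  freedom along the axis. Levenberg–Marquardt, ftol 1e-15, at most 200
  iterations; planar clouds are rejected as ill-conditioned.
* Moment arms use central differences with a 1e-5 rad step; entries for
  muscles that do not span a coordinate's joint are identically zero by
  construction, not by rounding.
* The active-set QP carries reserve columns at penalty 1e6 rather than
  something larger because the KKT system mixes muscle columns (order
  1e3) with reserve columns (order 1/penalty): pushing the penalty to 1e10
  drops the reserve contribution below machine precision and corrupts the
  multipliers. The exact polish step removes any dependence of the
  reported solution on the penalty value.
* Problem sizes used throughout the tests and the acceptance script: one
  walking trial of ~110 frames (69 stance frames), 200-point dome clouds,
  the full 54-path model, and the complete 114-perturbation sensitivity
  table. These sizes keep a full validation run in the minutes range on a
  single CPU while leaving every code path exercised at full model
  complexity.

## Known limitations

* Rigid per-segment mapping of muscle points (no MRI-based refinement
  step); the residuals quantify, per patient, how much that assumption
  costs.
* Ligaments are inert; contact, wrapping and muscle dynamics are out of
  scope.
* The knee hinge ignores tibiofemoral translations unless coupling
  coefficients are supplied.
* The toe-segment marker set is minimal (one marker for one coordinate),
  which is sufficient for the synthetic protocol but fragile under real
  marker noise near the MTP axis.
* Reported joint loads are resultants at the ankle; knee and hip loads are
  computed internally but are not a validated output of this package.
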