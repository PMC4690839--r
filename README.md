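# mskfoot

Patient-specific foot and ankle musculoskeletal modelling in R.

Chronic inflammatory joint disease in children — juvenile idiopathic
arthritis most prominently — frequently involves the ankle, and altered
joint loading is suspected to drive structural damage. Estimating the ankle
joint reaction force (JRF) during walking therefore matters clinically, but
scaled generic adult models misrepresent juvenile foot geometry: moment
arms, the ankle axis and muscle attachments can all be badly off. `mskfoot`
implements a modelling pipeline that builds a lower-limb model with a
**patient-specific foot and ankle** from routinely collectable data —
segmented MRI bone surfaces of the foot plus standard clinical gait
analysis — and quantifies, through three sensitivity protocols, which of
its modelling choices the estimated ankle load actually depends on.

The package is aimed at movement-biomechanics researchers who want a fully
scriptable, dependency-light implementation of this pipeline, with a
synthetic-patient generator so every stage can be validated against known
ground truth without any clinical data.

## What it computes

A generic lower-limb template (17 degrees of freedom: 6 pelvis, 3 hip,
1 knee, 3 ankle, 3 hindfoot–forefoot, 1 forefoot–toes; 54 muscle paths
describing 39 muscles, 16 crossing the ankle or internal foot joints; 7
inert ligament records) is deformed onto a patient by:

1. **Virtual palpation + Horn registration** — per-segment closed-form
   rigid registration (quaternion least squares) of named bone landmarks
   carries the generic muscle attachment and via points onto the patient's
   foot geometry (hindfoot 10, talus 6, metatarsal 15, toe 17 landmarks).
2. **Cylinder-fit ankle axis** — a least-squares cylinder fitted to the
   talar dome defines the ankle joint centre (midpoint of the fitted axial
   extent) and flexion/extension axis.
3. **Anthropometric scaling** — pelvis (depth/height/width), femur and
   shank scaled from a time-averaged static trial.
4. **Marker registration chain** — static foot markers onto radio-opaque
   MRI marker replicas; leg and pelvis markers onto palpated targets; femur
   rotated about the knee flexion axis to close the greater-trochanter gap.

Simulation then runs, per walking trial and windowed to stance:
marker-driven inverse kinematics (per-frame nonlinear least squares),
ground-reaction assignment under a one- or two-segment foot assumption
(1SEG/2SEG, switching at the metatarsophalangeal axis crossing of the
centre of pressure), quasi-static inverse dynamics, tendon-excursion moment
arms, static optimization

&nbsp;&nbsp;&nbsp;&nbsp; minimize Σᵢ aᵢ²  subject to  Σᵢ aᵢ·Fmaxᵢ·rᵢⱼ = τⱼ, 0 ≤ aᵢ ≤ 1,

solved exactly by a primal active-set method (with optional heavily
penalized reserve actuators), and joint reaction analysis:

&nbsp;&nbsp;&nbsp;&nbsp; **F**ⱼᵣf = **F**intersegmental − Σᵢ fᵢ **d̂**ᵢ,

reported as resultant magnitude in percent body weight (%BW). The
hindfoot/forefoot coordinates and ankle internal/external rotation are
locked during the optimization.

Three sensitivity protocols mirror the questions a modeller must answer:
GRF segment assignment (2SEG − 1SEG difference series), ankle frame
definition (image-based cylinder axis vs. the malleolar-marker frame,
including the reserve-actuator fallback when the marker frame makes the
optimization infeasible), and ±5 mm one-at-a-time perturbations of every
muscle point adjacent to the ankle, reported as mean and maximum percent
change of the JRF over stance.

## Worked example

```r
library(mskfoot)

template <- build_template()
template
#> <msk_model> 'generic lower limb + three-segment foot'
#>   7 segments, 7 joints, 17 DoFs (0 locked)
#>   54 muscle paths (39 distinct muscles, 16 crossing the ankle/foot), 7 ligaments (inert)
#>   19 markers, 61 landmarks; patient 75.0 kg, 1.75 m (BW 736 N)

# a synthetic juvenile patient with known ground truth
sp <- make_synthetic_patient(synthetic_foot_params(seed = 42))
model <- assemble_patient_model(template, sp$patient)
provenance(model)[c(2, 5, 9), ]
#>                stage rms_mm                                                   note
#> 2            scaling     NA  pelvis (0.830, 0.830, 0.830), femur 0.830, shank 0.830
#> 5  register_hindfoot   7.50
#> 9       cylinder_fit   0.00                                        radius 0.0166 m

walk <- make_walking_trial(synthetic_gait_params(seed = 43), model)
res <- run_pipeline(model, walk$trial, pipeline_config(mode = "1SEG", axes = "MR"))
res
#> <gait_result> 1SEG / MR_axes, 69 stance frames
#>   peak ankle JRF 458.2 %BW at 72% stance; IK residual 0.00 mm rms
plot(res)   # resultant ankle JRF over stance (%BW)
```

The 7.5 mm hindfoot registration residual is the cost of mapping adult
generic anatomy rigidly onto a child-sized foot; the zero-residual cylinder
fit recovers the generating dome radius (16.6 mm) exactly. The peak ankle
JRF of 4.6 body weight at 72% stance sits where push-off loads the
Achilles tendon, inside the 4–6 BW range typical of walking.

Sensitivity of the JRF to muscle placement:

```r
tab <- sensitivity_table(model, list(walk$trial))
print(tab)   # structures with |mean %change| >= 0.5%: achilles, tib_ant, ...
```

The Achilles insertion dominates: moving it 5 mm changes the mean JRF by
several percent, an order more than most other ankle-crossing points.

## Command line

```sh
Rscript inst/cli/mskfoot.R make-synthetic --out data/ --seed 42
Rscript inst/cli/mskfoot.R build-model --landmarks data/landmarks.json \
    --dome data/dome.ply --static data/static.trc \
    --mri-markers data/mri_markers.json --out patient.json
Rscript inst/cli/mskfoot.R run-gait --model patient.json --trc data/walk1.trc \
    --grf data/walk1.mot --mode 1SEG --axes MR --out results/
Rscript inst/cli/mskfoot.R sensitivity --model patient.json --trc data/walk1.trc \
    --grf data/walk1.mot --out results/
```

All interchange formats are plain text: TRC (markers), MOT/STO (forces and
result series), JSON (models, landmarks), ASCII PLY (bone surfaces).

See the methods vignette (`vignettes/foot-ankle-pipeline.Rmd`) for the
modelling assumptions, parameter choices and known limitations.
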