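Package: mskfoot
Title: Patient-Specific Foot and Ankle Musculoskeletal Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific lower-limb musculoskeletal models with a
    three-segment foot from segmented bone geometry, virtually palpated
    landmarks and standard clinical gait analysis data, and estimates ankle
    joint reaction forces during walking. Provides closed-form Horn
    point-set registration, least-squares cylinder fitting to the talar dome
    for an image-based ankle axis, anthropometric scaling of the proximal
    segments, marker-driven inverse kinematics, quasi-static inverse
    dynamics, static optimization of the muscle redundancy problem and joint
    reaction analysis, together with sensitivity protocols for the ground
    reaction force segment assignment, the ankle joint frame definition and
    5-mm muscle point perturbations. A synthetic patient generator with
    known ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
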