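Package: kneeslope
Title: Posterior Tibial Slope Effects on Total Knee Arthroplasty Joint Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale musculoskeletal analysis of how posterior tibial slope (PTS)
    alters joint mechanics after total knee arthroplasty. Provides parametric
    triangle-mesh implant geometry with virtual implantation at a commanded slope,
    an elastic-foundation articular contact model with compartmental forces, contact
    moments and centre-of-pressure outputs, Blankevoort-type ligament bundles with
    slack-length calibration to a reference strain at full extension, knee-crossing
    muscle actuators with tendon-excursion moment arms, a quasi-static concurrent
    solver for muscle activations and secondary tibiofemoral/patellofemoral
    kinematics, synthetic level-walking and squat activity generators, and a PTS
    sweep pipeline with Spearman rank-correlation sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
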