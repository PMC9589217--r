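Package: kneegait
Title: Concurrent Musculoskeletal and Finite-Element Knee Contact Mechanics During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale concurrent musculoskeletal and finite-element analysis
    of the knee during the stance phase of gait. Generates parametric knee
    geometry (rigid bones, elastic cartilage layers, transversely isotropic
    wedge-profile menisci with radial-tear and total-meniscectomy variants)
    and synthetic marker/force-plate gait trials; runs inverse kinematics,
    inverse dynamics, cubed-activation static muscle-force optimization and a
    quasi-static penalty-contact finite-element solve of the tibiofemoral
    joint, coupled through a secondary-kinematics feedback loop. Reports
    meniscus shear and hoop stress fields, tear-tip stress series and tibial
    cartilage contact force and pressure partitions across an experiment
    matrix of intact, torn and meniscectomized knees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
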