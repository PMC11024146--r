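Package: meniscusdyn
Title: Dynamic-Elastic Modeling of Knee Meniscal Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling the menisci of the tibiofemoral joint as
    elastic, volume-preserving triangulated meshes that conform to the
    femoral condyles across knee flexion. Provides rigid Procrustes bone
    placement from sparse cortical point clouds, cartilage-layer
    construction from scaled thickness maps, template-tube meniscus
    generation and constrained elastic fitting, Principal Polynomial Shape
    Analysis (PPSA) for continuous flexion-indexed knee models,
    correspondence-based point-dependent displacement metrics, surface
    distance validation (RMSE/ASD/Hausdorff) with a leave-one-out cohort
    harness, and a synthetic knee cohort generator with medial-pivot
    femorotibial kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
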