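Package: vppgrf
Title: Predicting Per-Foot Ground Reaction Forces from Kinematics via the
    Virtual Pivot Point
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts three-dimensional per-foot ground reaction forces
    (GRFs) from whole-body kinematics using the virtual pivot point (VPP)
    concept: during double support the per-foot GRF lines of action are
    assumed to intersect at a point above the centre of mass, which turns
    the force-distribution problem into a small least-squares solve.
    Includes a contact-point centre-of-pressure model with smooth
    position/velocity transition functions, the VPP force-decomposition
    solver, body-weight-normalised RMSE evaluation with a VPPscale
    parameter sweep, zero-phase Butterworth preprocessing, CSV/YAML/JSON
    input-output, and a synthetic-trial generator (squat, inline lunge,
    walking) with ground-truth forces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
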