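Package: pitchload
Title: Shoulder Kinetics and Pain Association for Youth Baseball Pitching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes shoulder joint-reaction kinetics from 6-DOF motion-capture
    recordings of baseball pitching and relates the resulting peak anterior and
    peak proximal forces to reported shoulder pain. Provides zero-lag Butterworth
    filtering, functional glenohumeral joint-center estimation by least-squares
    pivot fitting, ISB-convention segment frames and Euler decompositions, pitch
    event detection (stride-foot contact, maximum external rotation, ball
    release), recursive Newton-Euler inverse dynamics over a four-link
    torso-arm chain, and a statistical layer with point-biserial correlation and
    single-predictor logistic regression fitted by iteratively reweighted least
    squares. A synthetic-data module generates forward-kinematics pitching
    motions with analytically known ground-truth forces and cohorts drawn from a
    published exposure-risk model, so the whole pipeline is testable without
    access to raw capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
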