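Package: ghfloat
Title: Floating-Center Glenohumeral Joint Kinematics from Marker Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying the coupled motion of the shoulder
    complex from optical motion-capture marker trajectories. The
    glenohumeral (GH) joint centre is estimated by a dual-cluster
    invariance regression (the centre has constant local coordinates in
    both the scapula and humerus marker-cluster frames), expressed in the
    ISB thorax anatomical frame, and its normalized displacement is fitted
    as phase-specific polynomial or rational functions of the humeral
    elevation angle. The fitted coupling drives a floating-centre forward
    kinematic model of the humerus. A synthetic motion-capture generator
    with full ground truth supports recovery and noise-response studies,
    and the Klopcar shoulder-girdle model is built in for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
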