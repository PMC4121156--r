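Package: softbiometry
Title: Height and Weight Estimation from Low-Frame-Rate Video of Walking Subjects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates two body-related soft-biometric traits from low-frame-rate
    indoor video: upright height by single-view metrology anchored on the camera
    height, and body weight by a 13-feature silhouette measurement vector fed to
    a single-hidden-layer feedforward network trained with Levenberg-Marquardt.
    Includes silhouette extraction by background differencing with suppressed
    Otsu thresholding and brightness/chromaticity shadow removal, head/torso/leg
    segmentation from horizontal-projection minima, rank-k identification from
    the (height, weight) descriptor with cumulative match characteristic curves,
    and a ground-truthed synthetic scene generator (pinhole camera, parametric
    walking humanoid, cast shadows, appearance changes) for end-to-end
    evaluation without access to enrolment data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
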