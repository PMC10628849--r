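Package: boxnoise
Title: Localization-Noise Modelling and Correction for Object-Detection
    Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying, synthesizing and correcting localization
    noise in bounding-box annotations of biological images. Matches clean
    against noisy Pascal VOC annotation sets and reports per-boundary errors,
    the root-mean-square relative error (gamma), size-binned dispersion with a
    through-origin slope fit, and boundary-error correlations. Synthesizes
    size-proportional Gaussian boundary noise at a chosen gamma, runs an
    iterative teacher-student annotation-correction loop over a pluggable
    corrector, curates pseudo-labels (score filtering, overlap resolution,
    control-class stripping), and scores detections with IoU and 11-point
    interpolated mAP@50. Includes a synthetic fixture generator so every
    component is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    graphics,
    stats,
    tools,
    utils,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
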