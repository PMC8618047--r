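Package: thermoparam
Title: Physiological Heat-Source Parameters from Breast Thermograms
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the depth, intensity and radius of an internal heat
    source from the radial surface-temperature profile around the hottest
    spot of an infrared breast thermogram, using the closed-form
    Depth-Intensity-Radius (D-I-R) inversion of the point-source bio-heat
    solution and Lorentz-curve least-squares fitting.  Builds the
    five-component physiological pattern vector {Tmax, d, q, R, theta},
    classifies normal versus abnormal thermograms with a radial-basis
    support-vector machine under stratified cross-validation, and scans the
    radial extraction distance of the region of interest for the position
    with the highest correct-classification rate.  Includes a synthetic
    thermogram and cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
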