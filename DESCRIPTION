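Package: sfxsight
Title: Explainable Hit Finding for Serial Crystallography Diffraction Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how convolutional neural network hit finders
    classify serial femtosecond crystallography detector frames. Generates
    labelled synthetic diffraction frames with known Bragg-peak ground truth
    in the five-class Blank / No crystal / Weak / Good / Strong structure,
    trains compact AlexNet-style and residual classifiers with a built-in
    CNN engine, evaluates them with confusion-matrix metrics, and explains
    predictions with Grad-CAM, guided backpropagation and layer
    representation inversion under alpha-norm and total-variation priors.
    A classical radial-threshold spot finder provides the hit-finding
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
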