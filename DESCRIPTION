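Package: picarc
Title: Reference-Curve-Constrained Independent Component Analysis for
    HPLC-DAD Chromatogram Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates a 3D HPLC-DAD chromatogram (wavelength by elution
    time absorbance matrix) into per-compound elution peaks and spectra
    without knowing the number of compounds in advance.  Each candidate
    compound is described by a unit-maximum Gaussian reference curve with
    integer centre and width parameters; a constrained fastICA fit scores
    every parameter pair by the squared distance between the extracted
    elution profile and its reference, and a niching (multi-areas) genetic
    algorithm locates all local minima of that fitness surface
    simultaneously.  Spectra are then recovered by a pseudo-inverse
    estimator.  Includes a synthetic chromatogram generator, CSV and
    MATLAB v5 matrix readers, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
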