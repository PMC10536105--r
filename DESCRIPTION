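Package: zonephot
Title: Zonal Ring Photometry for CCD Scattering Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for CCD photometric images acquired with
    ellipsoidal-reflector photometers. Detects the bright region of
    interest and its radial symmetry point, computes mean illuminance of
    the central circle and two concentric rings, fits an exponential
    illuminance-thickness model for transmitted light and a logarithmic
    model for reflected light per laser power level, and calibrates the
    fitted coefficients against laser power with polynomial regression.
    Includes a synthetic scattering-spot image generator so the whole
    pipeline can be validated by parameter recovery without real
    captures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
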