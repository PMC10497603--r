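Package: specband
Title: Signature-Band Extraction from Hyperspectral Fruit Images by
    Integrated-Gradients Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting fruit sugar content (degrees Brix) from
    hyperspectral reflectance images and for distilling the hundreds of
    narrow hyperspectral bands down to a handful of wide "signature" bands
    that a cheap multispectral instrument could measure. The package
    radiometrically calibrates raw frames against dark and white references,
    denoises spectra with a Savitzky-Golay filter, resamples hypercubes onto
    boxcar band grids of configurable bandwidth, trains small convolutional
    and feedforward regression networks with an RMSLE objective, scores each
    band by the absolute mean of integrated gradients of the trained model,
    and greedily selects six signature bands subject to a minimum
    wavelength-spacing rule. A synthetic-data generator with planted
    band-to-Brix structure makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
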