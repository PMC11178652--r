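Package: hsitta
Title: Test-Time Augmentation for Perfusion Shifts in Hyperspectral Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to mitigate perfusion-induced distribution shifts in
    hyperspectral imaging (HSI) based surgical scene segmentation without
    retraining the segmentation model. The package forward-simulates tissue
    diffuse-reflectance spectra from physiological parameters (oxygen
    saturation, blood volume fraction, scattering) with a diffusion
    approximation, resamples them through a digital twin of a 100-band
    visible/near-infrared camera, and assembles a large parameterized
    synthetic spectral database. Real hyperspectral pixels are matched to
    the database by exact nearest-neighbor search to retrieve per-pixel
    tissue parameters (the image's "digital twin"), out-of-distribution
    perfusion pixels are flagged by interquartile-range filtering of StO2
    and VHb, and flagged pixels are replaced by hybrid real/synthetic
    spectra so a frozen pixel-wise classifier recovers segmentation
    performance. Includes a labeled synthetic scene generator covering four
    perfusion states, segmentation scoring with hierarchical Dice
    aggregation, and domain-gap diagnostics (PCA embedding and kernel
    density estimates of per-image median spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    FNN,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
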