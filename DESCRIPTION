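Package: metawave
Title: Functional Microanatomy of Airway Epithelium from Micro-OCT Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the functional microanatomy of ciliated airway
    epithelium from calibrated cross-sectional micro-optical coherence
    tomography (micro-OCT) video: detection of oscillatory ciliary activity,
    ciliary beat frequency (CBF) by Fourier power-spectral analysis with
    peak-sharpness ranking, phase-map-based detection and quantification of
    metachronal wave coordination, airway surface liquid (ASL) and
    periciliary liquid (PCL) depth segmentation, and mucociliary transport
    (MCT) rate by particle tracking.  Includes a ground-truth synthetic
    micro-OCT video simulator for validation, percent-change and rank-sum
    summary statistics, and backward stepwise regression of MCT on its
    covariates including a metachrony-by-CBF interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
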