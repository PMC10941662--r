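Package: specmix
Title: Spectral Imaging and Linear Unmixing for Multiplexed HCR Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for 10-plex hybridization chain reaction (HCR) spectral
    imaging: construction of fluorophore and autofluorescence reference
    spectra from 1-plex and unlabeled samples, per-pixel non-negative
    least-squares linear unmixing of multi-excitation/multi-detector image
    stacks, signal-to-background estimation, qHCR subcellular-voxel relative
    quantitation, dHCR single-molecule dot detection and colocalization, and
    a forward simulator of spectral acquisition that provides ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
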