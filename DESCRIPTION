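Package: qibcr
Title: Quantitative Image-Based Cytometry of DNA Damage Foci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for quantitative image-based cytometry
    (QIBC) of DNA-damage responses in asynchronous cell populations:
    segmentation of interphase nuclei from a DNA stain, detection of
    sub-nuclear ionizing-radiation-induced foci (e.g. 53BP1, gammaH2AX),
    cell-cycle staging from DAPI/EdU/Cyclin A/H4K20me2 features with 1-D
    and 2-D gating, and single-cell normalization of damage readouts to
    DNA content. Ships a seeded synthetic-microscopy generator with full
    ground truth so every stage is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
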