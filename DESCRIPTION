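Package: parcelscope
Title: Object-Based Processing of Very-High-Resolution Imagery over Smallholder Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for multi-temporal very-high-spatial-resolution
    satellite imagery of smallholder agricultural landscapes: tree-crown blob
    detection with automatic scale selection, tie-point based co-registration of
    scene stacks onto a master image, metadata-driven cloud masking, blob-based
    tree masking, and per-field object-based extraction of spectral moments,
    vegetation indices and grey-level co-occurrence texture descriptors, with a
    make-like incremental pipeline driver. Includes a synthetic-scene simulator
    with full ground truth so the whole chain is testable without proprietary
    imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
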