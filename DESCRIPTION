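Package: rsa4d
Title: Backward Prediction of Root System Development from Time-Series
    X-ray CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measuring individual root growth from time-series
    three-dimensional X-ray computed-tomography scans of potted plants.
    Volumes are aligned by iterative-closest-point registration of point
    clouds built from high-intensity soil particles, and a root-system
    vector traced manually at the last time point is propagated backwards
    in time: a per-node overlap score against each earlier root-segmented
    volume locates how far each root had grown, yielding per-root
    elongation start/end days, daily lengths, root counts and elongation
    rates. Includes a synthetic soil-and-root phantom generator with full
    ground truth, a deterministic occupancy scorer, and a small trainable
    3D convolutional block discriminator with per-root fine-tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
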