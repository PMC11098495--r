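Package: hicmaptools
Title: Analysis of Binned Hi-C Contact Maps in the Cooler Schema
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for the analysis of sparse binned chromosome
    conformation capture (Hi-C / Micro-C) contact matrices stored in the
    cooler HDF5 schema. Implements distance-decay expected (P(s)) curves with
    exact masked-bin accounting and log-space smoothing, A/B compartment
    profiles by eigendecomposition of distance-adjusted maps, saddle
    (pairwise class-average) summaries, diamond-window insulation profiles
    with prominence-scored boundary calls, focal dot (loop) detection with
    convolution kernels and lambda-chunked FDR control, snippet extraction
    and pileups around anchors, per-bin coverage, seeded downsampling,
    adaptive multi-scale smoothing, and a synthetic contact-map generator
    with known ground truth for validation. All per-region analyses operate
    over genomic views: ordered, named, non-overlapping regions such as
    chromosome arms. A command-line interface mirrors the R API one-to-one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    Matrix,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
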