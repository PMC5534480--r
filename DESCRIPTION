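Package: brickvol
Title: Block-Pyramid Storage and Out-of-Core Processing for Large 3D
    Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stores terabyte-scale 3D grayscale microscopy volumes as a
    multi-resolution pyramid of fixed-size cubic blocks on disk, and
    processes them out of core: a memory-bounded reformatter that converts
    2D slice sequences into the block pyramid, a random-access region
    reader with automatic pyramid-level selection and a least-recently-used
    block cache, a block-wise rigid transformer that re-samples whole
    datasets through inverse mapping, orthogonal re-slicing with
    maximum-intensity projection, and a seeded 3D chessboard phantom
    generator for benchmarking. All geometric parameters are configurable
    so the full machinery runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tiff,
    parallel,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
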