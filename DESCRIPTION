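Package: mssit
Title: Multiscale Surface Vision Transformers for Cortical Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical vision-transformer backbone for signals living on
    sphericalised cortical meshes. Signals sampled on a 6th-order icosphere are
    partitioned into triangular patches using the next-coarser icosphere,
    processed with multi-head self-attention restricted to local mesh windows
    (with a shifted-window variant for cross-window information flow), and
    progressively merged four-to-one into a multiscale representation that
    supports whole-surface regression/classification as well as a U-shaped
    decoder for vertex-wise parcellation. Includes nested icosphere
    construction with canonical face/vertex ordering, GIFTI metric/label/surface
    input-output, barycentric resampling between spherical meshes, surface data
    augmentation (random rotations and coarse-grid elastic warps), a seeded
    training harness (AdamW, cosine decay, Dice plus cross-entropy or MSE
    losses, balanced sampling), and generators for synthetic spherical datasets
    with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
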