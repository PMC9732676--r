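Package: chunkvol
Title: Chunked Volume Processing for Dense 3D Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for processing large dense 3D segmentation and
    microscopy volumes stored in a Precomputed-style chunked layout: chunked and
    sharded volume storage with segmentation-specific codecs
    (compressed_segmentation block bit-packing and compresso boundary encoding),
    truncation-aware image pyramid downsampling, single-pass multi-label
    marching cubes meshing with one-voxel overlap stitching and
    topology-guarded quadric simplification, chunked TEASAR-style
    skeletonization with deterministic border-target stitching, two-pass
    per-slice contrast correction, an idempotent lease-based filesystem task
    queue, and dataset management operations (transfer, re-chunk, re-encode,
    delete, unsharded-to-sharded condensation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    png,
    stats,
    utils,
    tools
Suggests:
    EBImage,
    parallel,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
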