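Package: histoblob
Title: Blob Detection of Nuclear Lesions in H&E Breast Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic blob-detection pipeline for cancerous lesions in
    hematoxylin-and-eosin (H&E) stained breast histology images. The pipeline
    chains Macenko optical-density stain estimation and unmixing, geometric
    augmentation, threshold/morphology/distance-transform enhancement,
    connected-components grouping with a Laplacian-of-Gaussian kernel,
    geodesic active-contour (level set) boundary refinement, Hessian
    blobness scoring with a logistic selection model for false-positive
    elimination, and a small dense detection network. A seeded synthetic
    H&E scene generator with per-nucleus ground truth makes every stage
    testable without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
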