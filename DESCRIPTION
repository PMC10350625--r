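Package: gfcn
Title: Graph Fully Convolutional Networks for Ischemic Stroke Lesion
    Segmentation from CT Perfusion Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments ischemic stroke lesions from multi-modal CT
    perfusion parameter maps (non-contrast CT, CBF, CBV, MTT, Tmax) with
    a fully convolutional graph network.  Image slices are converted to
    pixel graphs with geometric pseudo-coordinates; trainable B-spline
    kernel graph convolutions, graph coarsening (Graclus matching, Top-k
    selection, farthest-point sampling) and heuristic unpooling
    operators (isotropic copy, proportional redistribution, inverse
    square distance kNN interpolation) are assembled into encoder
    decoder architectures with FCN-style additive score skips (32s, 16s,
    8s variants).  Includes soft Dice training with Adam, fourfold
    cross-validation, volume-wise and sample-wise evaluation (Dice,
    Hausdorff distance, precision, recall, accuracy, coefficient of
    determination) with lesion-size stratification, a seeded multi-modal
    pseudo-CTP phantom generator with NIfTI input and output, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
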