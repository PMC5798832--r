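Package: ctradiomics
Title: 3D CT Radiomics Feature Extraction and Nodule Signature Building
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: High-throughput 3D radiomics for lung-nodule CT: reads image
    volumes and binary region-of-interest masks (NIfTI/NRRD), extracts a
    750-feature inventory (intensity, shape, intensity-volume histogram,
    Laws texture-energy, wavelet and Laplacian-of-Gaussian filter banks,
    co-occurrence, run-length, size-zone, gray-tone difference and fractal
    features) and builds a benign/malignant signature by quantile
    normalization, Wilcoxon rank-sum screening and sequential forward
    selection wrapped around a support vector machine under leave-one-out
    cross-validation, with all-feature and random-signature baselines.
    Includes a synthetic nodule-phantom cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    e1071,
    igraph,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
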