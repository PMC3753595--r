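Package: lddmmseg
Title: Greedy LDDMM Registration and Multi-Atlas Subcortical Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Large deformation diffeomorphic metric mapping (LDDMM) image
    registration by greedy gradient descent on a time-dependent velocity
    field, with the Fourier-domain smoothing kernel induced by the operator
    L = -alpha * Laplacian + gamma * Id, a cascading scheme over decreasing
    alpha, single-atlas label propagation and multi-atlas EM likelihood
    fusion for subcortical segmentation, the kappa / volume-difference / L1
    overlap metrics, and a synthetic labeled-phantom generator with known
    ground-truth diffeomorphisms so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
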