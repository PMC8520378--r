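Package: cspa
Title: Compressed Sensing for Photoacoustic and Ultrasound A-Line Signals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for compressed-sensing acquisition and reconstruction of
    one-dimensional ultrasound and photoacoustic radio-frequency signals
    (A-lines).  Provides five orthonormal sparse bases (unitary DFT,
    orthonormal DCT-II, DST-I, discrete Hartley and the Wang discrete
    W-transform family), threshold-based sparsity profiling across bases,
    random measurement operators (Gaussian, Bernoulli, row subsampling) with
    mutual-coherence diagnostics, and sparse solvers (orthogonal matching
    pursuit, ISTA/FISTA proximal gradient, and an exhaustive l0 oracle for
    small instances).  A phantom module generates compressible test signals
    and synthetic photoacoustic A-lines, including a three-group
    contrast-enhancement experiment emulating laser-triggered phase-change
    nanoparticle contrast agents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
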