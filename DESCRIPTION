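Package: overlapfrp
Title: Overlap Correction for Eye-Fixation-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of overlapping evoked potentials from co-registered
    continuous neural recordings and event streams (stimulus onsets, fixation
    onsets). Implements and contrasts three estimators: classical time-locked
    averaging, the ADJAR iterative adjacent-response overlap correction, and
    multi-class general-linear-model deconvolution with sparse Toeplitz design
    matrices. Includes overlap diagnostics (lag distributions, first- and
    second-order overlap waveforms), condition-number and bootstrap-variance
    reporting, a synthetic session generator for validation by parameter
    recovery, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
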