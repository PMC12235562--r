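Package: apershift
Title: Event-Related Aperiodic EEG Analysis: Cue-Induced Spectral Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for event-related changes in the aperiodic
    (1/f^x) component of epoched EEG. Provides windowed FFT power spectra
    with removal of the phase-locked (ERP) spectrum, fixed-mode spectral
    parameterization with iterative Gaussian peak removal, cue-induced
    spectral-shift statistics with sign-flip permutation mixed ANOVAs,
    behavioral dependent variables (reaction time, error rate, inverse
    efficiency), and rank-based (Wilcoxon-score) regressions linking
    spectral shifts to performance. Includes a synthetic-data generator
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rhdf5,
    RcppTOML
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
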