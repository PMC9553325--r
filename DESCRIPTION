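Package: stimclean
Title: Periodic Stimulation-Artifact Removal for Gapped Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes high-amplitude periodic stimulation artifacts (such as
    those produced by deep brain stimulation devices) from uniformly sampled
    single-channel recordings that are broken into segments by missing data
    of unknown length. The artifact is modelled as a truncated Fourier
    series with an unknown fundamental frequency and unknown per-segment
    phase shifts; the linear amplitudes are eliminated in closed form
    (variable projection) and the remaining frequency and phase parameters
    are estimated by a safeguarded Newton descent, initialized by
    multi-start modified-Newton ascent on a cross-segment alignment energy.
    Handles aliased (sub-Nyquist) stimulation frequencies. Includes
    synthetic-data generators, a DFT peak-energy baseline, evaluation
    metrics, spectral reports, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
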