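Package: nbfr
Title: Non-Negative Basis Function Regression for Holographic Photostimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps optogenetic receptive fields (ORFs) from holographic
    ensemble-stimulation calcium-imaging responses by adaptive non-negative
    basis function regression, and repositions two-dimensional stimulation
    sites by analytic-gradient ascent so that target neurons are activated
    while off-target activation of neighbouring neurons is minimised. Includes
    the grid-based ORF-mapping protocol designer (redundancy removal, batching
    into multi-target trials with inter-trial spacing constraints,
    pseudo-single-target extraction and physiological point-spread-function
    estimation), a simulation framework with heterogeneous super-Gaussian
    ground-truth receptive fields, imaging noise and optional sparse excitatory
    recurrence, and paired somatic-versus-optimized benchmarking of off-target
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
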