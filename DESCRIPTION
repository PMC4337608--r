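Package: neuromosaic
Title: Quantification of Somatic Copy-Number Mosaicism in Single Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting somatic genomic
    mosaicism in single neuronal nuclei. Implements standard-curve qPCR
    amplification-efficiency calibration, delta-delta-Ct relative copy-number
    (RCN) estimation with replicate-based confidence intervals, a modeled
    confidence-interval copy-number caller with integer bins 1-6 and ">6",
    flow-cytometry DNA-content-variation (DCV) analysis (G0/G1 peak
    statistics, CEN-normalized DNA index, NeuN gating, group tests), FISH
    aneusomy count statistics, and PNA-FISH puncta intensity thresholding.
    A synthetic-data module generates every input the pipeline consumes,
    with matched truth tables, so all stages are testable end to end.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
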