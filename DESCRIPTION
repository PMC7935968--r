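Package: methanokin
Title: Closed-Batch Gas-Conversion Kinetics for Hydrogenotrophic Methanogens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying CH4 production kinetics of hydrogenotrophic
    methanogens grown in sealed (closed batch) vessels on H2/CO2 headspace gas.
    Converts logged headspace pressure decay into methane evolution rates
    (MER), substrate turnover, maximum pressure-drop slopes (k_min), and
    active-window summary statistics; segments repetitive closed batch (RCB)
    logs into individual conversion cycles; estimates specific growth rates
    and biomass increase rates from optical density series; runs the
    multivariate screening stage (iterative-PCA imputation, standardized PCA,
    k-means on the leading components); scans MCR alpha-subunit alignments
    for the Tyr444-Gly445-Tyr446 motif with reference-based residue
    numbering; and simulates closed-batch and RCB methanogenesis so that the
    whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
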