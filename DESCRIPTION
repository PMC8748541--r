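Package: dropscan
Title: Droplet-Microfluidic Deep Mutational Scanning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of droplet-sorting deep mutational
    scans of enzymes. Simulates error-prone PCR variant libraries,
    Poisson-loaded droplet encapsulation and fluorescence-gated sorting,
    and paired sequencing pools; calls amino-acid substitutions from reads
    against a coding reference; estimates per-substitution fitness
    coefficients by positive-unlabeled logistic regression with a known
    class prior; aggregates coefficients into per-site mutational
    tolerance and cross-paralog divergence profiles; and fits
    Hill-equation enzyme kinetics with active-site titration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
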