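Package: EpiPacemaker
Title: Closed-Form Epigenetic Pacemaker and Molecular Clock Models for
    DNA Methylation Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the molecular clock (MC) and epigenetic pacemaker (EPM)
    models to CpG methylation matrices. The MC model assumes each site's
    methylation level is linear in chronological age; the EPM relaxes this
    by estimating a per-individual epigenetic age. Both conditional
    maximization steps of the alternating (CEM) fit are computed in closed
    form from the structure of the normal equations, giving O(nm) time and
    space per iteration without forming any design matrix. Includes a
    likelihood-ratio test between the nested models, a seeded simulator for
    both generative models, delimited-text input/output with Pearson-based
    site selection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: DNAMethylation, Epigenetics, Regression, Software, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
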