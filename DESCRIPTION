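Package: lncnetsig
Title: lncRNA-mRNA Co-Expression Networks and Prognostic lncRNA Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression-filtered lncRNA-mRNA Pearson
    co-expression networks with connected-component modules and hub
    statistics (degree, betweenness, power-law degree fit); survival
    screening of network lncRNAs by maximally selected cutpoints with
    Kaplan-Meier and log-rank tests; multivariate Cox proportional-hazards
    risk signatures with high/low-risk stratification and time-dependent
    ROC; and lncRNA-to-cancer-hallmark association through network mRNA
    neighbors, their GO terms and a GO-to-hallmark mapping. Includes a
    synthetic-data generator that emulates a tumor/normal bulk
    transcriptome study with block-correlated modules, planted fold
    changes and proportional-hazards survival, plus an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
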