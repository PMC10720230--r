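Package: comorbnet
Title: Multimorbidity Network Analysis of Inpatient ICD-10 Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds multimorbidity networks from baseline inpatient
    hospitalization records coded in ICD-10. Screens all pairwise
    comorbidity patterns by odds ratio with Bonferroni control and a
    prevalence floor, constructs undirected disease networks, computes
    node centralities including maximal clique centrality, identifies
    hub diseases and their associated networks, and produces
    population-comparison summaries. Includes a synthetic-cohort
    generator with planted pairwise odds ratios so every stage can be
    validated by parameter recovery without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
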