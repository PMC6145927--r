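Package: statefate
Title: Cell-State Transition Dynamics and Drug-Tolerant Persister Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of drug-tolerant persister cell-state
    dynamics in basal-like breast cancer. Provides marker-based cell-state
    gating downstream of image cytometry, Shannon-diversity and geneset-based
    heterogeneity metrics, drug-screen phenotype profiling with dose-response
    characterization (Emax/Einf), Chou-Talalay combination indices, and a
    hypothesis-constrained linear time-invariant birth/death/transition model
    fitted by constrained l2-regularized least squares with alternating
    minimization, used to discriminate Darwinian selection from
    transition-mediated enrichment of persister states. A synthetic-data
    module generates every input with known ground truth so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    fgsea,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
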