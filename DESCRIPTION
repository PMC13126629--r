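Package: pkaladder
Title: Curation, Transition Assignment and Benchmarking of Macroscopic pKa Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling experimental acid dissociation constant (pKa)
    collections into per-molecule, per-charge-state-transition reference values
    and for benchmarking pKa predictors against them. Experimental macroscopic
    pKa values are annotated with charge-state transitions by order-preserving,
    L1-minimal matching against predicted macro-pKa ladders (with window,
    closest-value and two-value linear-assignment variants); multi-source
    collections are curated by pKb conversion, cosolvent/condition filtering,
    outlier exclusion, cross-source deduplication and per-transition averaging;
    curated molecules are classified into monoprotic, amphoteric and polyprotic
    benchmark sets; predictor output ladders are scored with MAE/RMSE, binned
    error histograms and exception rates, and predictor pairs are compared by
    one-way ANOVA with a five-test post-hoc majority vote. A seeded synthetic
    data generator emulates noisy replicate measurements, undetected
    transitions and imperfect predictor ladders so the whole pipeline is
    testable without external databases. Structure handling (InChI keys,
    Morgan fingerprints, substructure search) is delegated to the RDKit
    toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH.
Config/testthat/edition: 3
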