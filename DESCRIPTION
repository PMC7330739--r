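Package: eagl
Title: Spectral Summarization and Sparse Learning of Temporal Graphical
    Models of Chronic Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns sparse temporal Bayesian networks of multiple
    chronic condition (MCC) emergence from patient-year binary cohorts,
    and summarizes existing graphical models by pruning edges whose
    removal least perturbs the second-smallest eigenvalue (algebraic
    connectivity) of the graph Laplacian. Provides K2/AIC structure
    scores with a lambda * lambda2 spectral penalty, greedy
    depth-first-search-protected edge pruning with and without
    supporting data, exact inference by variable elimination, ROC/AUC
    cross-validated evaluation of year-ahead comorbidity prediction,
    and seeded synthetic cohort and lexicon-graph generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
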