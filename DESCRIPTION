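Package: noctivox
Title: Nocturnal Vocal Activity Analysis from Passive Acoustic and
    Behavioral Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nocturnal vocal activity of group-living
    diurnal animals monitored with passive acoustic recorders and
    synchronized night-vision video. Computes the Acoustic Complexity Index
    (ACI) from audio in fixed time windows, builds vocal events from call
    timestamps with a short-gap merge rule and behavioral contexts, derives
    social-network and dominance metrics (dyadic association index,
    eigenvector centrality, David's Scores with K-means rank tiers, kinship
    counts), classifies hourly activity into peak/normal/trough by a
    quartile rule, and fits the inferential models: a Poisson mixed model of
    per-individual call counts with a collinearity screen, generalized
    additive models of ACI on weather covariates with candidate-model
    selection and backward smooth removal, and a Friedman test of behavioral
    rhythms. A synthetic-data generator produces night soundscapes, call and
    behavior logs, social observation records, and weather series from known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    mgcv,
    lme4,
    igraph
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
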