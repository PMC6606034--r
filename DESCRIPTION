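Package: claimnet
Title: Replicability of Published Claims via High-Throughput Evidence and
    Collaboration Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the replicability of published drug-gene interaction
    claims against high-throughput perturbational expression signatures.
    Combines per-condition moderated z-scores into a single effect per
    interaction (Stouffer aggregation with bootstrap confidence intervals),
    scores literature support with a uniform-prior binomial Bayesian model
    sampled by Metropolis-Hastings, contrasts observed replication rates
    with a permutation-null baseline (relative replication increase),
    quantifies social, methodological and knowledge independence of the
    community around each claim via Jaccard-weighted multilayer networks,
    measures authorship centralization with the Gini coefficient of the
    bipartite author-paper network, and relates all of these to replication
    success through logistic regression with Benjamini-Hochberg correction.
    Ships a synthetic-corpus generator with known ground truth so the whole
    pipeline is exercisable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
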