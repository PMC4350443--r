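Package: belnet
Title: Causal Biological Network Curation with BEL, Reverse Causal
    Reasoning and Crowd Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for building and maintaining causal biological
    network models written in a restricted dialect of the Biological
    Expression Language (BEL). Provides a BEL term and statement parser
    with canonicalization against function and namespace registries,
    versioned network models with evidence, context annotations and
    provenance, a reverse-causal-reasoning engine that selects state
    changes from differential-expression tables and scores candidate
    upstream mechanisms by hypergeometric richness and binomial
    concordance, a crowd-verification engine implementing chronological
    vote ledgers with a four-vote locking rule and leaderboards, network
    agglomeration with evidence-conserving edge collapsing, BEL-script
    and XGMML input/output, and deterministic synthetic-data generators
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
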