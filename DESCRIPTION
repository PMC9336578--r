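Package: dahnet
Title: Network Analysis of Development Assistance for Health Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying development assistance for health (DAH) as an
    evolving directed weighted network. Builds annual source-to-channel and
    channel-to-recipient networks from disbursement flow tables, classifies
    actors with a public/private/CSO/PPP typology, computes degree metrics and
    a tuning-parameter generalization of closeness centrality for weighted
    directed graphs, and summarises the funding landscape (totals, node and
    edge counts, proportional category shares, rankings). Includes a seeded
    synthetic flow generator that emulates the structural features of
    source-channel-recipient disbursement data for fully reproducible,
    download-free analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
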