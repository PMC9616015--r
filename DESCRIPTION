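Package: orgnet
Title: Whole-Network Analysis of Interorganizational Service Delivery Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative whole-network analysis of
    interorganizational service delivery systems, built around client-referral
    and contact surveys of organizational boundary spanners. Reads rosters and
    respondent-level tie reports, collapses respondents to organizations,
    handles survey nonresponse by labeled reconstruction (column transposition
    of missing rows), symmetrizes directed reports under the any-link rule,
    and computes differentiation and integration metric panels (active
    organizations, isolates, ties, density, average degree, Freeman degree
    centralization), ranked degree-centrality tables, and sector-level
    aggregations with fourfold connection-strength coding. A synthetic survey
    generator based on a core-periphery block model provides fully specified
    test-beds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
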