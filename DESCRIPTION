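Package: msea
Title: Microbe-Set Enrichment Analysis with Themed Set Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds themed microbe-set libraries from taxonomy lineages,
    literature co-mention corpora and disease-microbe curation exports, and
    tests input microbe lists against them. The enrichment statistic couples a
    one-sided Fisher's exact test under a fixed microbe universe with a
    Monte-Carlo expected-rank z-score correction and a combined score, and the
    package provides bipartite-graph, overlap-network and t-SNE embedding
    reports together with seeded synthetic-data generators for every input it
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
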