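Package: pulsecube
Title: Multidimensional Analysis of Health-Related Social Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for public-health infoveillance over micro-blog streams.
    Reads day-resolution post streams in a compact JSON Lines dialect,
    scores users by vocabulary diversity (Yule's I) and domain coherence
    against a pluggable medical-term lexicon, detects short bursty events
    and sustained topics from bigram daily time series via excess-kurtosis
    thresholds, clusters co-occurring terms into event/topic groups by
    graph modularity, classifies user profiles from account descriptions
    with a small feed-forward network, and aggregates post and user facts
    into OLAP-style report tables (quality, audience, first-person and
    reply rates). A seeded synthetic-stream generator with ground truth
    makes every stage testable without live platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    nnet,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
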