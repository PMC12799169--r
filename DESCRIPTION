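Package: netcoord
Title: Agent-Based Coordination Games on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairwise coordination games (the minimal Name Game and
    Context-Aware Agents that mix prior knowledge with social context) on
    homogeneously mixed and spatially embedded networks, and provides the
    accompanying measurement suite: dominant-response convergence, normalized
    response entropy, per-trial decision-strategy classification, per-token
    coordination rates, and an embedding-based narrative-alignment score built
    from cosine similarities passed through a temperature-scaled softmax.
    Transcripts are tidy tables suitable for downstream regression modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
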