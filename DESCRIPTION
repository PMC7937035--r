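Package: songnet
Title: Directed Syllable-Sequence Networks for Birdsong
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterises the sequential organisation of birdsong by
    representing syllable sequences as directed networks. Builds per-song
    adjacency matrices summed over a recording, computes classical and
    network descriptors (repertoire size, syllable count, average degree,
    average shortest path, clustering coefficient, small-worldness),
    contrasts them with within-song permutation null models via Cohen's d
    pooled by random-effects meta-analysis, detects cross-song motif types,
    estimates repeatability of the descriptors from mixed models with
    parametric bootstrap intervals, and relates them to male quality and
    fitness proxies with linear and binomial models. Includes a synthetic
    song generator with individual-specific grammars and known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
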