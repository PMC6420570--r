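Package: motifweb
Title: Motif Representation in Probabilistic Grassland Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds probabilistic plot-level food webs from a trophic metaweb
    combined with abundance-dependent encounter probabilities, samples binary
    webs, enumerates the 13 connected three-species motifs (directed triads),
    benchmarks motif counts against degree-preserving Curveball null models,
    and computes normalised motif significance profiles along an experimental
    plant-diversity gradient. Includes a synthetic community generator that
    emulates the design of a grassland biodiversity experiment (sown richness
    levels 1-60 over 80 plots in 4 blocks and 4 sampling periods) so the whole
    pipeline runs without field data, and linear mixed models for richness
    trends in motif counts and normalised scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    lmerTest,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
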