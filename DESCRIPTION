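Package: betabench
Title: Property-Based Benchmarking of Abundance-Based Beta-Diversity Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hypothetical species assemblages under a Fisher
    log-series abundance distribution and manipulates them (species turnover,
    rank decoupling, evenness redistribution, nested species loss, species
    replication, abundance rescaling, without-replacement subsampling) to
    benchmark pairwise beta-diversity metrics.  Implements a registry of 29
    presence-absence and abundance-based dissimilarity indices plus the
    Baselga and Podani turnover/nestedness partitions of Bray-Curtis and
    Ruzicka dissimilarity, a harness that scores every metric against
    conceptual, sampling and personality properties, and scorecard
    aggregation with Pareto-dominance analysis and principal component
    analysis of the quantitative scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vegan, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
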