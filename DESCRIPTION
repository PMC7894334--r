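Package: linfam
Title: Lineage-Resolved Gene Family Evolution from Gene Trees, Synteny
    and Sequence Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions a bootstrap-annotated gene tree into ancestral
    homolog lineages by explicit clade-content criteria, reconciles the
    lineages against a clade-annotated species tree to count copy-number
    gains and losses, classifies homolog pairs as tandem, syntenic or
    dispersed by parameterised collinearity chaining, and summarises
    per-lineage sequence statistics (conserved-region similarity,
    protein lengths, Nei-Gojobori Ka/Ks).  A birth-death gene family
    simulator with full ground-truth event logs makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
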