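Package: crypticdelim
Title: Integrative Delimitation of Cryptic Species from Multilocus Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discovering and diagnosing cryptic
    species from multilocus DNA sequence alignments. Implements uncorrected
    pairwise distances with a relative (2x) threshold test for species
    discovery, statistical-parsimony haplotype networks with a
    probability-of-parsimony connection limit and gaps treated as a fifth
    character state, gene-tree concordance assessment, a combined multi-line
    evidence rule yielding per-clade species hypotheses, nucleotide-based
    diagnostic characters in dual (alignment and type-specimen) coordinates,
    Tajima's D, and substitution-saturation diagnostics. A coalescent-based
    multilocus simulator with known species structure makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
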