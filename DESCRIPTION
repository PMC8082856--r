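Package: haplotigr
Title: Ploidy-Agnostic Phasing of Long Reads into Haplotigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases polyploid genomes of any ploidy from long-read alignments
    by iteratively clustering reads reduced to their base calls at known
    heterozygous SNP positions. Cluster consensus is computed by
    context-coverage-weighted voting, and a cluster-identity-maintenance rule
    stops merging when clusters become too dissimilar, so the number of
    haplotypes emerges from the data rather than being supplied. Includes a
    split-read stitching pass to improve haplotig contiguity, a three-step
    automated cleaning procedure (discordance-gated merging, low-coverage
    filtering, gap filling), truth-based accuracy and contiguity metrics,
    truth-free diagnostics (windowed coverage profiles, in-cluster allele
    frequency distributions), and a seeded synthetic polyploid read simulator
    for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
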