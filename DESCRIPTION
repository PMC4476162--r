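Package: splicesel
Title: Selection on Exonic Splice-Associated Cis-Motifs Within and Between Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies purifying selection on exonic splice enhancers (ESEs)
    at internal exon flanks as a function of intron size and density. Provides
    gene-model parsing and filtering from GFF3/FASTA, hexamer masking of
    69-bp exon-end flanks, Nei-Gojobori (NG86) synonymous substitution rate
    estimation with Jukes-Cantor correction over equal-count intron-size bins,
    nucleotide-matched pseudo-ESE null sets, positional codon/amino-acid usage
    trend statistics near exon-intron junctions, splice-site usage proportions,
    Watterson/pi/eta theta estimators for per-site Ne.mu, phylogenetically
    controlled Brownian-motion trait correlation via independent contrasts,
    Goodman-Kruskal gamma with permutation p-values, intragene decoy-splice-site
    tests, and a synthetic-data generator so every stage is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    Matrix,
    ape,
    jsonlite,
    yaml,
    digest,
    generics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
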