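Package: repeatphylo
Title: Phylogenetic Inference from Genomic Repeat Abundances
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phylogenetic trees from the genomic abundance of
    repetitive DNA families estimated by graph-based clustering of
    low-coverage (genome skimming) sequence reads. Reads from multiple
    taxa are trimmed, sampled to an equal genome proportion, and
    clustered on a sequence-similarity graph by maximum modularity;
    per-taxon read counts per cluster become continuous phylogenetic
    characters. Trees are inferred by continuous-character Wagner
    parsimony (Farris interval down-pass, Goloboff-style up-pass,
    implicit enumeration, symmetric resampling supports) and by
    maximum likelihood under a Brownian-motion drift model with
    bootstrap supports. Includes ground-truthed synthetic-data
    generators and method-performance experiments (genome-proportion
    titration, cluster-number titration, matrix partitions, repeat-type
    informativeness), plus TNT/Hennig86 continuous-matrix export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
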