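Package: nbsprofiler
Title: Genome-Wide Characterization of Plant NBS-LRR Resistance Genes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for genome-wide profiling of the plant
    NBS-LRR (nucleotide-binding site, leucine-rich repeat) resistance gene
    family. Classifies NBS genes into the CNL/TNL/RNL groups and their nine
    domain-architecture subclasses, scans the eight conserved NBS-domain
    motifs (P-loop through MHDL) and judges motif-order conservation, calls
    chromosomal gene clusters with a 250-kb chaining rule, classifies
    duplication origins (whole-genome/segmental, tandem, proximal,
    dispersed), estimates Ka/Ks selection pressure with the Nei-Gojobori
    (1986) pathway-counting method, and profiles FPKM expression across
    fruit tissues and developmental stages. Ships a synthetic genome
    simulator with planted ground truth (subclasses, clusters, duplication
    types, codon pairs evolved at chosen Ka/Ks, negative-binomial counts)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
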