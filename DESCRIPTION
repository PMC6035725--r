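Package: corseqr
Title: Favoured Codon Detection from Raw RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies an organism's translationally favoured (optimal)
    codons directly from raw RNA-seq reads, without a genome, annotation or
    expression quantification. Reads are assigned a coding frame and
    orientation by matching their translations against an amino-acid kmer
    index built from a protein training set; frame-aligned nucleotide kmers
    counted across the resulting pseudo-ORFs serve as an expression proxy,
    and per-codon 2x2 contingency tests between the high- and low-frequency
    kmer tails call the favoured codons. Also provides the conventional
    expression-method baseline (codon usage of the most- versus
    least-expressed coding sequences), comparison metrics between methods,
    replicate-concordance summaries, and a ground-truthed synthetic
    transcriptome and read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
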