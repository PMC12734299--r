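Package: anidelim
Title: Fragment-Based Average Nucleotide Identity, Species Delimitation, and
    Mating-Type Locus Analysis for Fungal Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-based species delimitation in filamentous fungi.
    Computes reciprocal fragment-based average nucleotide identity (ANI)
    between assemblies with per-fragment identity histograms and
    specific-sequence (zero-hit) fractions, applies threshold rules with an
    identity-spectrum exception for conspecific pairs carrying a minority of
    highly divergent regions, extracts ITS/LSU barcode regions from
    assemblies and counts pairwise differences, classifies mating-type (MAT)
    locus architecture from gene annotations with contig-edge reassembly and
    a read-coverage ratio test for homothallism versus heterothallism, and
    simulates genome pairs, rDNA cassettes, MAT-locus fixtures and per-gene
    coverage tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb) on the PATH
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
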