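Package: snpmapper
Title: Remapping SNP Probes onto Reference Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps short probe sequences representative of single nucleotide
    polymorphisms (SNPs) onto reference chromosome sequences to recover an
    unambiguous absolute chromosomal position per SNP. Each SNP's allele
    group is collapsed to a single placeholder read which is aligned by a
    three-stage pipeline: a complete mismatch-bounded ungapped search with
    an optional gapped dynamic-programming rescue, a sensitive
    Smith-Waterman rescue stage, and a resolution stage that filters
    allele-inconsistent placements, corrects edit distances, selects best
    hits with explicit ambiguity semantics, and resolves the SNP base's
    reference coordinate from the CIGAR string. Includes readers for
    Illumina-style manifests and probe FASTA/info files, and a synthetic
    fixture generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    Biostrings,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
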