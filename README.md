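# snpmapper

Remapping SNP probes onto reference chromosomes.

## The problem

Genotyping arrays ship with mapping files that assign each SNP a
chromosomal position, but those coordinates are tied to a particular
genome build, carry no provenance about how they were obtained, and are
occasionally simply wrong. Downstream association analyses are sensitive
to such errors, so before merging datasets or moving to a new build it
pays to re-derive every SNP's position directly from its probe sequence.

`snpmapper` does exactly that. A SNP whose probe is written as flanking
sequence around a bracketed allele group, e.g.

```
GCACTCTCACATGGATTAGGGAATTA[CG]ATGCAGACCTCCTGCACAACTGCCC
```

is collapsed to a **single placeholder read** `left + ? + right`, where
the placeholder scores as a mismatch against every reference base. One
alignment per SNP therefore covers all alleles (for a biallelic SNP this
roughly halves the alignment work), at the price of a post-hoc filter:
any placement where the reference base under the placeholder matches
none of the SNP's alleles (complement-adjusted on the reverse strand) is
a **false positive** and is removed, and accepted placements get a
**corrected edit distance** `raw − 1` that refunds the guaranteed
placeholder mismatch.

## The pipeline

Each probe runs through three stages, restricted first to its
vendor-declared chromosome (Pass A) and genome-wide afterwards for
anything unresolved or vendor-unmapped (Pass B):

1. **Stage 1 — complete mismatch-bounded search.** All placements on
   both strands with Hamming distance ≤ *k* (default 4, placeholder
   included) are found by pigeonhole seeding: the read is split into
   *k*+1 contiguous segments, any placement within budget must contain
   an exact segment, and segment seeds are looked up in a complete k-mer
   occurrence index of the reference. If nothing qualifies, a unit-cost
   semi-global DP rescues gapped placements (mismatches ≤ *k*, gap
   bases ≤ 10).
2. **Stage 2 — Smith–Waterman rescue.** Reads still unmapped or
   ambiguous are re-aligned locally with affine gaps under the scheme
   match +10, mismatch −15, gap open −33, gap extend −33, with no cap on
   the number of alignments. Hits must cover the placeholder.
3. **Stage 3 — resolution.** Allele filtering, edit-distance correction,
   best-hit selection (stage 1 by corrected edit distance, stage 2 by SW
   score) with explicit ambiguity semantics — a tie at the top means
   `ambiguous` with MAPQ 0, never an arbitrary winner — and the SNP's
   absolute coordinate recovered by walking the CIGAR from the
   alignment start, strand-adjusted.

Every verdict is one of `unique`, `ambiguous`, `unmapped` or
`allele_filtered`, with mapped position, strand, CIGAR, corrected edit
distance, MAPQ and stage of origin.

## Worked example

```r
library(snpmapper)

g  <- generateGenome(nChroms = 2, lengths = c(50000, 30000), seed = 42)
ex <- plantProbes(g, n = 4, mutation = "exact",               seed = 1, idPrefix = "ex")
mm <- plantProbes(g, n = 3, mutation = "mismatches", nMismatches = 2, seed = 2, idPrefix = "mm")
del<- plantProbes(g, n = 2, mutation = "indel", indelType = "del",    seed = 3, idPrefix = "del")
ai <- plantProbes(g, n = 2, mutation = "allele_inconsistent", seed = 4, idPrefix = "ai")
probes <- c(ex$probes, mm$probes, del$probes, ai$probes)

res <- runPipeline(probes, g, verbose = TRUE)
#> mapped 9 / 11 uniquely; 0 ambiguous, 0 unmapped, 2 allele-filtered (0 rescued at stage 2)
mappedSnps(res)[, c("snp_id", "status", "mapped_pos", "cigar",
                    "corrected_edit_distance", "stage")]
```

```
  snp_id          status mapped_pos    cigar corrected_edit_distance      stage
  ex0001          unique      37569      53M                       0 1-ungapped
  mm0001          unique      37600      53M                       2 1-ungapped
 del0001          unique      25254 38M1D14M                       1   1-gapped
 del0002          unique      41378 10M1D42M                       1   1-gapped
  ai0001 allele_filtered         NA     <NA>                      NA       <NA>
```

(abridged; 11 rows in total). The exact probes come back with corrected
distance 0 at their planted coordinates; probes with two planted flank
mismatches come back with corrected distance 2; probes with a 1-base
flank deletion are rescued by the gapped stage with the deletion visible
in the CIGAR and the SNP coordinate unshifted; probes whose alleles both
contradict the reference base are filtered rather than placed.
`compareToDeclared(res)` then audits the mapped positions against the
vendor's coordinates (here: 9 identical, 2 unmapped).

A command-line front end with the same capabilities lives at
`inst/cli/snpmapper.R`:

```sh
Rscript inst/cli/snpmapper.R convert-manifest chip.csv --out-prefix probes
Rscript inst/cli/snpmapper.R map --reference ref.fa \
    --probes probes.fa --info probes.info.tsv --out results.tsv -D
Rscript inst/cli/snpmapper.R compare results.tsv
```

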