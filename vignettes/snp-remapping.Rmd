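---
title: "Remapping SNP probes: model, parameters and design notes"
author: "snpmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remapping SNP probes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The single-read model of a SNP

A genotyping probe describes a SNP as flanking sequence around a
bracketed allele group, `LEFT[A1A2]RIGHT`. Two representations are
possible: one read per allele, aligned independently, or one read for
the whole SNP with the allele group replaced by a placeholder character
that mismatches every reference base. `snpmapper` implements the second:
it needs roughly half the alignment work for biallelic SNPs, at the cost
of two extra obligations that the resolution stage discharges:

* **allele filtering** — a placement is only believable if the reference
  base under the placeholder is one of the declared alleles (its
  complement on the − strand, since the aligned read there is the
  reverse complement of the probe);
* **edit-distance correction** — every placement that covers the
  placeholder pays one guaranteed mismatch, so the corrected distance is
  `raw − 1`. Corrected distance 0 therefore means "the flanks match the
  reference exactly".

Internally the placeholder is `?`, deliberately distinct from `N`: an
`N` in a flank is a genuinely ambiguous base (which also never matches),
while the placeholder marks the variant column whose reference
coordinate is the whole point of the exercise. In the two-file probe
representation (FASTA + info table) the placeholder is written as `N`
for FASTA-alphabet compliance and re-identified on reading via the
`snp_offset` column, so flank Ns and the placeholder never collide.

Coordinates are 1-based and fully closed everywhere (the convention of
both SAM and Illumina's `MapInfo`).

## The three stages

**Stage 1 (ungapped, complete).** All placements on both strands with
Hamming distance at most `maxMismatches` are enumerated — no heuristic,
no seed-and-extend loss. The guarantee comes from pigeonhole seeding:
split the read into `maxMismatches + 1` contiguous segments; any
placement within budget must render at least one segment exactly.
Segments whose leading k-mer contains `N` or the placeholder are
excluded from seeding, which is safe because each such segment is itself
forced to contribute a mismatch, strengthening the pigeonhole argument
for the rest. Candidate placements implied by seed-index hits are then
verified by direct mismatch counting. Reads too short to supply
`maxMismatches + 1` seeds of length `seedLen` are scanned by brute force
instead, preserving completeness. The completeness claim is tested
against an independently coded brute-force oracle on thousands of random
reads.

**Stage 1 (gapped rescue).** Only when the ungapped search finds
nothing. Each seeded candidate window (read length plus `gapMargin` on
each side) is aligned semi-globally — read end-to-end, reference ends
free — under unit edit costs. A placement is accepted when its mismatch
count (placeholder included) stays within `maxMismatches` *and* its
total gapped bases stay within `gapMargin`. The two budgets are
deliberately separate: a gapless read with five mismatches must not
sneak through on the strength of an unused gap allowance.

**Stage 2 (Smith–Waterman rescue).** For reads unmapped or ambiguous
after stage 1. Local alignment with affine gaps under the published
scheme (match +10, mismatch −15, gap open −33, gap extend −33; a
length-g gap costs `open + extend·(g−1)`, the convention in which the
open penalty is charged once). No cap is applied to the number of hits
at this stage. Two filters apply: the local alignment must cover the
placeholder (otherwise the allele cannot be checked and the SNP
coordinate is undefined — such hits are discarded rather than extended),
and it must reach `swMinScoreFrac` (default 0.55) of the maximum
attainable score `match × read length`. The floor exists because the
stage is uncapped: without it, arbitrarily weak local hits anchored by a
single 10-mer would enter best-hit selection as MAPQ competitors.
Clipped read ends are recorded on the hit (`clip_left`/`clip_right`) and
excluded from the edit distance. Although gapped alignment is enabled
here by default (the gap penalties would otherwise be dead
configuration), `gaplessStage2 = TRUE` restricts the stage to ungapped
local alignments.

**Stage 3 (resolution).** `snpRefPosition()` walks the CIGAR from the
leftmost consumed reference base using the strand-adjusted read offset
(`offset` on +, `readLen − 1 − offset` on −, shifted by any left clip);
M consumes both sequences, I only the read, D only the reference. A
placeholder falling inside an insertion run is unresolvable and the hit
is rejected with reason `in_insertion`; a reference `N` under the
placeholder is unverifiable (`ref_N`). Best-hit selection ranks stage-1
hits by corrected edit distance and stage-2 hits by SW score. A shared
top key is reported as `ambiguous` with MAPQ 0 — the pipeline never
breaks such ties arbitrarily, because an unverifiable position is worse
than no position.

**MAPQ.** The aligners this design descends from report a BWA-like
mapping quality whose exact formula is pair-oriented and unpublished;
the pipeline relies only on its order semantics (tie ⇒ ambiguous,
larger best-to-second gap ⇒ more confident). A documented monotone
surrogate preserves exactly that: 60 for a sole hit, 0 for a tie,
otherwise `min(60, round(60·(k₂−k₁)/maxMismatches))` at stage 1 and
`min(60, round(60·(S₁−S₂)/S₁))` at stage 2.

**Passes.** Pass A aligns each probe only against its declared
chromosome — wrong-chromosome annotations are rare enough that the
restriction is a large constant-factor saving — and always has stage 2
available. Pass B re-runs everything unresolved, plus vendor-unmapped
probes and probes whose declared chromosome is absent from the reference
(a warning, not an error), against the whole genome; there stage 2 runs
only under the `genomeWideStage2` ("D") flag, because an uncapped
genome-wide Smith–Waterman pass is the single most expensive operation
the pipeline can perform. Disabling "D" can therefore only move Pass-B
outcomes from `unique` to `unmapped`, never change Pass A — a property
the test suite asserts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxMismatches` | 4 | stage-1 Hamming budget, placeholder included; effective flank budget is 3 |
| `maxHits` | 1000 | stage-1 per-read cap, applied after deterministic ordering and **before** allele filtering |
| `enableGappedStage1` | TRUE | run the semi-global rescue when ungapped search fails |
| `gapMargin` | 10 bases | window margin and maximum detectable indel length |
| `seedLen` | 10 | k-mer length of the reference index |
| `swMatch/swMismatch/swGapOpen/swGapExtend` | 10/15/33/33 | stage-2 score scheme |
| `swMinScoreFrac` | 0.55 | stage-2 acceptance floor as a fraction of the maximum score |
| `gaplessStage2` | FALSE | restrict stage 2 to ungapped local alignments |
| `workers` | 1 | probes are distributed over forked workers; results are worker-count-invariant |
| `genomeWideStage2` | FALSE | the "D" option |

The placeholder consuming one unit of the mismatch budget is worth
restating: with the default budget of 4, at most 3 real flank mismatches
survive stage 1. `gapMargin = 10` reflects probe geometry — probes are
~50–130 nt, and a flank harbouring a longer indel no longer localises
the SNP trustworthily.

## Numerical and tie-breaking choices

* **Determinism.** Hits are ordered by chromosome order as loaded, then
  start, then strand (+ before −) before capping; DP tracebacks use a
  fixed preference (M over D over I, gap states close as early as
  possible, leftmost end on ties). Two runs on identical input produce
  byte-identical output files.
* **Co-optimal alignments.** Under unit costs (and under equal
  open/extend penalties) two families of co-optimal paths are actively
  harmful: paths that bury the placeholder inside an insertion run
  (the hit would then be rejected as unresolvable), and paths that split
  one gap into several runs (which can shift the SNP coordinate by a
  base inside repeats). Both aligners therefore use epsilon-layered
  internal costs — the true cost/score scaled up, a small rebate for
  keeping the placeholder on a reference base, a one-point surcharge per
  gap opening. The layering is provably too small to change the optimal
  cost or score; it only selects, among genuinely co-optimal alignments,
  the one whose interpretation is well-defined. Reported costs and
  scores are recomputed on the published scheme.
* **Cap timing.** The stage-1 cap applies at alignment time, before the
  allele filter. A SNP with 1000+ placements is unresolvable either
  way, so the cap's only practical effect is bounding memory; capping
  early keeps the aligner's contract independent of probe annotation.
* **Degenerate inputs.** Reference `N` never matches any read base. A
  seed k-mer containing `N` is not indexed. Chromosomes shorter than
  `seedLen` are skipped with a warning (an error only if *every*
  chromosome is too short). Reads too short to seed fall back to brute
  force. Empty probe sets round-trip through the writers.

## What the synthetic fixtures emulate — and what they do not

`generateGenome()` draws uniform i.i.d. A/C/G/T sequence, optionally
copying windows verbatim to create exact decoy duplications;
`plantProbes()` cuts probes from the genome (flank 26 by default,
matching typical probe half-width), makes the centre base one allele,
draws the second allele different from the reference (or both different,
for deliberately allele-inconsistent probes), and perturbs flanks with a
stated number of mismatches or a 1–2 nt indel, never touching the
placeholder and staying ≥3 bases from read ends and ≥5 from flank ends
(so the perturbation count is recoverable from the corrected edit
distance and the indel stays visible in the CIGAR, instead of being
absorbed by local-alignment end effects). Every planted probe's context
is verified by brute force at generation time — uniqueness within the
Hamming budget for probes expected `unique`, at least two placements for
probes expected `ambiguous`, zero ungapped placements for indel probes —
so the expected statuses are decidable, not hopeful.

Real genomes are not i.i.d.: repeat families, segmental duplications,
GC skew and assembly gaps (`N` runs) all make real probes harder, and
real manifests contain indel and multi-base polymorphisms that this
package deliberately does not model (single-base, 2–4-allele SNPs
only). Passing the fixture suite therefore demonstrates the
*correctness of the machinery* — completeness of the search, exactness
of coordinate arithmetic, soundness of the filters — not a sensitivity
claim on any particular chip or build. On real data the ambiguity and
unmapped rates are properties of the genome and probe design, not of
this implementation.

The test sizes (20 genomes × 200 reads for the completeness oracle, 500
random pairs for the Smith–Waterman oracle, 1000 probes in a 1 Mb
genome for planted recovery, 100 indel probes, 200 allele-inconsistent
probes, 50 duplication probes) were chosen as the smallest sets at which
each property is exercised across all code paths with comfortable
statistical margin; they complete in a few minutes on one CPU.

## Design decisions that were genuinely open

* **Manifest sequence column.** Illumina manifests carry the bracket
  construct in more than one column; the reader takes a configurable
  column name with `TopGenomicSeq` as the documented default (it is the
  column in top-strand orientation, the orientation `MapInfo` refers
  to). Vendor strand columns are ignored entirely: orientation is
  discovered by aligning both strands, which is self-validating.
* **Allele dialects.** Both `[CG]` and `[C/G]` are accepted and
  normalised to a base set.
* **Info-file dialect.** Tab-delimited with a commented header
  (`#snp_id chrom pos alleles snp_offset`), `.` for absent values —
  fixed here since only "a flat file" is specified by convention.
* **Stage independence.** Stages are resolved independently: stage 2
  strictly overrides only when stage 1 produced no unique hit. MAPQ
  values are never compared across stages (their scales differ).
* **`allele_filtered` as a distinct status.** A SNP all of whose
  placements fail the allele check is diagnostically different from one
  with no placements at all; the statuses are kept separate in the
  output and collapsed into "unmapped" only in the audit summary.
* **Heuristic-free Pass B.** The genome-wide re-run uses the same
  complete stage-1 search as Pass A; no additional heuristics are
  layered on top.

## Known limitations

* No indel polymorphisms inside the allele construct; single-base
  alleles only.
* Quadratic, scalar DP kernels — correctness-first, appropriate for
  probe-length reads (≤ ~130 nt), not for NGS-scale read sets.
* No base-quality awareness (probe sequences carry none) and no
  paired-end logic.
* Indels longer than `gapMargin` (10) are undetectable by design.
* Stage 2's sliding-window fallback (used only when no seed anchors
  anywhere) is quadratic in reference length and intended for small
  references; on a full genome an unseedable read is effectively
  unmappable at this stage.
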