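#' @useDynLib snpmapper, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# The single placeholder character substituted for the allele group in a
# collapsed probe read. Distinct from 'N' so that genuine ambiguous flank
# bases are never confused with the variant site.
PLACEHOLDER <- "?"

DNA_BASES <- c("A", "C", "G", "T")

#' SnpProbeSet: a set of SNP probes
#'
#' Holds, per SNP: identifier, left/right flanking sequences, the allele
#' set (1-4 distinct bases), and the vendor-declared chromosome and 1-based
#' position (either may be absent, modelling vendor-unmapped SNPs).
#'
#' @slot snpId character vector of SNP identifiers.
#' @slot leftFlank,rightFlank uppercase DNA flanks (A,C,G,T,N).
#' @slot alleles list of character vectors of distinct bases.
#' @slot declaredChrom declared chromosome names (NA when absent).
#' @slot declaredPos declared 1-based positions (NA when absent).
#' @exportClass SnpProbeSet
setClass("SnpProbeSet",
  representation(
    snpId = "character",
    leftFlank = "character",
    rightFlank = "character",
    alleles = "list",
    declaredChrom = "character",
    declaredPos = "integer"
  )
)

setValidity("SnpProbeSet", function(object) {
  n <- length(object@snpId)
  lens <- c(length(object@leftFlank), length(object@rightFlank),
            length(object@alleles), length(object@declaredChrom),
            length(object@declaredPos))
  if (any(lens != n)) return("slot lengths differ")
  if (anyDuplicated(object@snpId)) return("duplicate snp_id")
  if (any(grepl("[^ACGTN]", object@leftFlank)) ||
      any(grepl("[^ACGTN]", object@rightFlank)))
    return("flanks may contain only A,C,G,T,N")
  if (n > 0 && any(nchar(object@leftFlank) == 0 & nchar(object@rightFlank) == 0))
    return("left and right flank must not both be empty")
  for (a in object@alleles) {
    if (length(a) < 1 || length(a) > 4 || anyDuplicated(a) ||
        !all(a %in% DNA_BASES))
      return("alleles must be 1-4 distinct bases from A,C,G,T")
  }
  TRUE
})

#' Construct a SnpProbeSet
#'
#' @param snpId SNP identifiers (unique).
#' @param leftFlank,rightFlank DNA flank sequences (case-insensitive).
#' @param alleles list of character vectors of alleles, or a character
#'   vector like \code{"C/G"}.
#' @param declaredChrom,declaredPos vendor-declared chromosome/position;
#'   use NA for vendor-unmapped SNPs.
#' @return A \linkS4class{SnpProbeSet}.
#' @examples
#' SnpProbeSet("rs1", "ACGT", "TTAA", list(c("C", "G")))
#' @export
SnpProbeSet <- function(snpId, leftFlank, rightFlank, alleles,
                        declaredChrom = NA_character_,
                        declaredPos = NA_integer_) {
  n <- length(snpId)
  if (is.character(alleles)) alleles <- strsplit(toupper(alleles), "/", fixed = TRUE)
  new("SnpProbeSet",
      snpId = as.character(snpId),
      leftFlank = toupper(as.character(leftFlank)),
      rightFlank = toupper(as.character(rightFlank)),
      alleles = alleles,
      declaredChrom = rep_len(as.character(declaredChrom), n),
      declaredPos = rep_len(as.integer(declaredPos), n))
}

#' @describeIn SnpProbeSet number of probes
#' @param x a SnpProbeSet
#' @export
setMethod("length", "SnpProbeSet", function(x) length(x@snpId))

#' @export
setMethod("[", "SnpProbeSet", function(x, i, j, ..., drop = TRUE) {
  new("SnpProbeSet",
      snpId = x@snpId[i], leftFlank = x@leftFlank[i],
      rightFlank = x@rightFlank[i], alleles = x@alleles[i],
      declaredChrom = x@declaredChrom[i], declaredPos = x@declaredPos[i])
})

#' @export
setMethod("c", "SnpProbeSet", function(x, ...) {
  parts <- c(list(x), list(...))
  new("SnpProbeSet",
      snpId = unlist(lapply(parts, slot, "snpId")),
      leftFlank = unlist(lapply(parts, slot, "leftFlank")),
      rightFlank = unlist(lapply(parts, slot, "rightFlank")),
      alleles = do.call(c, lapply(parts, slot, "alleles")),
      declaredChrom = unlist(lapply(parts, slot, "declaredChrom")),
      declaredPos = unlist(lapply(parts, slot, "declaredPos")))
})

setMethod("show", "SnpProbeSet", function(object) {
  n <- length(object)
  cat("SnpProbeSet with", n, "probes\n")
  if (n > 0) {
    w <- probeWidth(object)
    cat("  read widths:", min(w), "-", max(w), "\n")
    cat("  vendor-unmapped:", sum(is.na(object@declaredPos)), "\n")
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s [%s] %s:%s\n", object@snpId[i],
                  paste(object@alleles[[i]], collapse = "/"),
                  object@declaredChrom[i], object@declaredPos[i]))
    }
    if (n > k) cat("  ...\n")
  }
})

#' @export
as.data.frame.SnpProbeSet <- function(x, ...) {
  data.frame(snp_id = x@snpId, left_flank = x@leftFlank,
             right_flank = x@rightFlank,
             alleles = vapply(x@alleles, paste, "", collapse = "/"),
             declared_chrom = x@declaredChrom, declared_pos = x@declaredPos,
             stringsAsFactors = FALSE)
}

#' @rdname SnpProbeSet-accessors
#' @param x a SnpProbeSet
#' @export
snpId <- function(x) x@snpId
#' @rdname SnpProbeSet-accessors
#' @export
leftFlank <- function(x) x@leftFlank
#' @rdname SnpProbeSet-accessors
#' @export
rightFlank <- function(x) x@rightFlank
#' Accessors for SnpProbeSet
#'
#' @name SnpProbeSet-accessors
#' @return vectors or lists parallel to the probes.
#' @rdname SnpProbeSet-accessors
#' @export
alleleList <- function(x) x@alleles
#' @rdname SnpProbeSet-accessors
#' @export
declaredChrom <- function(x) x@declaredChrom
#' @rdname SnpProbeSet-accessors
#' @export
declaredPos <- function(x) x@declaredPos
#' @rdname SnpProbeSet-accessors
#' @export
probeWidth <- function(x) nchar(x@leftFlank) + 1L + nchar(x@rightFlank)

#' ReferenceGenome: chromosome sequences plus a seed index
#'
#' Chromosome sequences are stored uppercase; the optional seed index maps
#' every fixed-length A/C/G/T substring to its 1-based occurrences and
#' supports the complete mismatch-bounded search of the stage-1 aligner.
#' Coordinates throughout the package are 1-based and fully closed.
#'
#' @slot sequences named character vector of uppercase chromosome sequences.
#' @slot seedIndex a data.table (kmer, chrom, pos) keyed by kmer, or NULL.
#' @slot seedLen the indexed k-mer length (NA when unindexed).
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
  representation(sequences = "character", seedIndex = "ANY",
                 seedLen = "integer"))

setValidity("ReferenceGenome", function(object) {
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("chromosome names must be present and unique")
  if (any(nchar(object@sequences) == 0))
    return("chromosome sequences must be non-empty")
  if (any(grepl("[^ACGTN]", object@sequences)))
    return("sequences may contain only A,C,G,T,N")
  TRUE
})

#' Construct a ReferenceGenome from named sequences
#'
#' @param sequences named character vector of chromosome sequences.
#' @return An unindexed \linkS4class{ReferenceGenome}.
#' @export
referenceGenome <- function(sequences) {
  sequences <- toupper(sequences)
  sequences <- chartr("U", "T", sequences)
  new("ReferenceGenome", sequences = sequences, seedIndex = NULL,
      seedLen = NA_integer_)
}

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome with", length(object@sequences), "chromosome(s),",
      sum(nchar(object@sequences)), "bp total\n")
  cat("  seed index:",
      if (isIndexed(object)) paste0("k = ", object@seedLen) else "none", "\n")
})

#' @rdname ReferenceGenome-accessors
#' @param g a ReferenceGenome
#' @export
seqNames <- function(g) names(g@sequences)
#' Accessors for ReferenceGenome
#'
#' @name ReferenceGenome-accessors
#' @rdname ReferenceGenome-accessors
#' @export
seqLengths <- function(g) stats::setNames(nchar(g@sequences), names(g@sequences))
#' @rdname ReferenceGenome-accessors
#' @param name chromosome name
#' @export
getChromSeq <- function(g, name) {
  if (!name %in% names(g@sequences)) stop("unknown chromosome: ", name)
  unname(g@sequences[[name]])
}
#' @rdname ReferenceGenome-accessors
#' @export
isIndexed <- function(g) !is.null(g@seedIndex)

#' PipelineConfig: every tunable of the mapping pipeline
#'
#' Defaults follow the published operating point of the tool being
#' modelled: up to 4 mismatches in the ungapped stage-1 search (the
#' placeholder consumes one), at most 1000 stage-1 hits per read,
#' Smith-Waterman scoring 10 / -15 / -33 / -33 at stage 2, and the
#' genome-wide stage-2 fallback ("D" option) off.
#'
#' @slot maxMismatches stage-1 Hamming budget, 1-4 (placeholder included).
#' @slot maxHits stage-1 per-read hit cap (applied after deterministic
#'   ordering, before filtering).
#' @slot enableGappedStage1 run the gapped DP rescue when the ungapped
#'   search finds nothing.
#' @slot gapMargin reference-window margin for gapped alignment; also the
#'   maximum detectable indel length.
#' @slot seedLen seed k-mer length for the index.
#' @slot swMatch,swMismatch,swGapOpen,swGapExtend stage-2 score scheme
#'   (penalties are positive numbers; a length-g gap costs
#'   open + extend*(g-1)).
#' @slot swMinScoreFrac stage-2 hits must score at least this fraction of
#'   the maximum attainable score (match * read length).
#' @slot gaplessStage2 restrict stage 2 to ungapped local alignments.
#' @slot workers CPU workers for per-probe distribution.
#' @slot genomeWideStage2 the "D" option: run stage 2 during the
#'   genome-wide re-run (Pass B).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    maxMismatches = "integer", maxHits = "integer",
    enableGappedStage1 = "logical", gapMargin = "integer",
    seedLen = "integer",
    swMatch = "integer", swMismatch = "integer",
    swGapOpen = "integer", swGapExtend = "integer",
    swMinScoreFrac = "numeric", gaplessStage2 = "logical",
    workers = "integer", genomeWideStage2 = "logical"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@maxMismatches < 1L || object@maxMismatches > 4L)
    return("maxMismatches must be in 1..4")
  if (object@maxHits < 1L) return("maxHits must be positive")
  if (object@seedLen < 4L) return("seedLen must be >= 4")
  if (object@swMismatch < 0L || object@swGapOpen < 0L || object@swGapExtend < 0L)
    return("penalties must be non-negative")
  if (object@workers < 1L) return("workers must be positive")
  if (object@swMinScoreFrac < 0 || object@swMinScoreFrac >= 1)
    return("swMinScoreFrac must be in [0,1)")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param maxMismatches,maxHits,enableGappedStage1,gapMargin,seedLen
#'   stage-1 tunables, see \linkS4class{PipelineConfig}.
#' @param swMatch,swMismatch,swGapOpen,swGapExtend,swMinScoreFrac,gaplessStage2
#'   stage-2 tunables.
#' @param workers,genomeWideStage2 orchestration tunables.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(maxMismatches = 3)
#' @export
pipelineConfig <- function(maxMismatches = 4, maxHits = 1000,
                           enableGappedStage1 = TRUE, gapMargin = 10,
                           seedLen = 10,
                           swMatch = 10, swMismatch = 15,
                           swGapOpen = 33, swGapExtend = 33,
                           swMinScoreFrac = 0.55, gaplessStage2 = FALSE,
                           workers = 1, genomeWideStage2 = FALSE) {
  new("PipelineConfig",
      maxMismatches = as.integer(maxMismatches),
      maxHits = as.integer(maxHits),
      enableGappedStage1 = isTRUE(enableGappedStage1),
      gapMargin = as.integer(gapMargin),
      seedLen = as.integer(seedLen),
      swMatch = as.integer(swMatch), swMismatch = as.integer(swMismatch),
      swGapOpen = as.integer(swGapOpen), swGapExtend = as.integer(swGapExtend),
      swMinScoreFrac = as.numeric(swMinScoreFrac),
      gaplessStage2 = isTRUE(gaplessStage2),
      workers = as.integer(workers),
      genomeWideStage2 = isTRUE(genomeWideStage2))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat("  stage 1: <=", object@maxMismatches, "mismatches, cap",
      object@maxHits, "hits, seed", object@seedLen,
      if (object@enableGappedStage1) ", gapped rescue on" else ", gapped rescue off",
      "\n")
  cat("  stage 2: SW ", object@swMatch, "/-", object@swMismatch, "/-",
      object@swGapOpen, "/-", object@swGapExtend,
      if (object@gaplessStage2) " (gapless)" else "", "\n", sep = "")
  cat("  genome-wide stage-2 fallback (\"D\"):",
      if (object@genomeWideStage2) "on" else "off", "\n")
})

#' SnpMapResult: per-SNP mapping verdicts
#'
#' One row per input probe, in input order, with status
#' unique / ambiguous / unmapped / allele_filtered, the mapped position
#' (present iff unique), strand, CIGAR, corrected edit distance, MAPQ,
#' stage of origin and pipeline pass.
#'
#' @slot mapping the per-SNP data.frame.
#' @slot config the \linkS4class{PipelineConfig} used.
#' @exportClass SnpMapResult
setClass("SnpMapResult",
  representation(mapping = "data.frame", config = "PipelineConfig"))

setMethod("show", "SnpMapResult", function(object) {
  m <- object@mapping
  cat("SnpMapResult for", nrow(m), "SNPs\n")
  tab <- table(factor(m$status,
                      levels = c("unique", "ambiguous", "unmapped", "allele_filtered")))
  for (s in names(tab)) cat(sprintf("  %-16s %d\n", s, tab[[s]]))
  if (any(m$status == "unique"))
    cat("  stages of unique calls:",
        paste(names(table(m$stage[m$status == "unique"])), collapse = ", "), "\n")
})

#' @rdname SnpMapResult-class
#' @param x a SnpMapResult
#' @return \code{mappedSnps} returns the per-SNP data.frame.
#' @export
mappedSnps <- function(x) x@mapping

#' @export
as.data.frame.SnpMapResult <- function(x, ...) x@mapping
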