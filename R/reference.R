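#' Load reference chromosomes from FASTA
#'
#' Multi-record FASTA; chromosome names are the first whitespace-delimited
#' token of each header. Sequences are uppercased, U is normalised to T,
#' and any residual non-A/C/G/T character (IUPAC ambiguity codes) is
#' mapped to N. Duplicate names or empty records are errors.
#'
#' @param path FASTA file path.
#' @return An unindexed \linkS4class{ReferenceGenome}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgu"), fa)
#' loadReference(fa)
#' @export
loadReference <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in ", path, ": ", nm[duplicated(nm)][1])
  s <- toupper(as.character(seqs))
  s <- chartr("U", "T", s)
  s <- gsub("[^ACGTN]", "N", s)
  referenceGenome(stats::setNames(s, nm))
}

#' Write a ReferenceGenome to FASTA
#'
#' @param g a \linkS4class{ReferenceGenome}.
#' @param path output path.
#' @return invisibly, \code{g}.
#' @export
writeReference <- function(g, path) {
  seqs <- Biostrings::DNAStringSet(g@sequences)
  Biostrings::writeXStringSet(seqs, path)
  invisible(g)
}

#' Build the seed index
#'
#' Indexes every occurrence of every length-\code{seedLen} substring over
#' A,C,G,T of every chromosome (substrings containing N are not indexed).
#' The index supports the complete pigeonhole-seeded mismatch-bounded
#' search of the stage-1 aligner and the candidate-window discovery of
#' stage 2.
#'
#' @param g a \linkS4class{ReferenceGenome}.
#' @param seedLen k-mer length, >= 4.
#' @return \code{g} with the index attached.
#' @examples
#' g <- buildSeedIndex(referenceGenome(c(chr1 = "ACGTACGT")), seedLen = 4)
#' seedLookup(g, "ACGT")
#' @export
buildSeedIndex <- function(g, seedLen = 10) {
  seedLen <- as.integer(seedLen)
  if (seedLen < 4L) stop("seedLen must be >= 4")
  lens <- nchar(g@sequences)
  if (all(lens < seedLen))
    stop("seedLen (", seedLen, ") is longer than every chromosome")
  parts <- vector("list", length(g@sequences))
  for (i in seq_along(g@sequences)) {
    L <- lens[i]
    if (L < seedLen) {
      warning("chromosome ", names(g@sequences)[i],
              " is shorter than seedLen and is not indexed")
      next
    }
    n <- L - seedLen + 1L
    km <- substring(g@sequences[[i]], seq_len(n), seq_len(n) + seedLen - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    parts[[i]] <- data.table::data.table(
      kmer = km[ok], chrom = names(g@sequences)[i], pos = which(ok))
  }
  idx <- data.table::rbindlist(parts)
  data.table::setkeyv(idx, "kmer")
  new("ReferenceGenome", sequences = g@sequences, seedIndex = idx,
      seedLen = seedLen)
}

#' Look up seed occurrences
#'
#' @param g an indexed \linkS4class{ReferenceGenome}.
#' @param kmers character vector of length-\code{seedLen} seeds.
#' @return data.frame with columns kmer, chrom, pos (1-based starts,
#'   sorted by chromosome order then position within each seed).
#' @export
seedLookup <- function(g, kmers) {
  if (!isIndexed(g)) stop("genome has no seed index; call buildSeedIndex()")
  if (any(nchar(kmers) != g@seedLen))
    stop("seeds must have the indexed length ", g@seedLen)
  hits <- g@seedIndex[data.table::data.table(kmer = unique(kmers)), nomatch = NULL]
  out <- as.data.frame(hits)
  ord <- order(match(out$chrom, names(g@sequences)), out$pos)
  out[ord, , drop = FALSE]
}
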