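# Stage 1: complete mismatch-bounded ungapped search via pigeonhole
# seeding over the k-mer index, with an optional gapped DP rescue.

.normRead <- function(read) {
  if (is.character(read) && length(read) == 1L) {
    seq <- toupper(read)
    off <- regexpr("?", seq, fixed = TRUE)
    if (off < 0) stop("read carries no placeholder '?'")
    return(list(snp_id = "read1", seq = seq, offset = as.integer(off) - 1L))
  }
  if (is.data.frame(read)) {
    if (nrow(read) != 1L) stop("one read at a time")
    read <- as.list(read)
  }
  list(snp_id = as.character(read$snp_id), seq = toupper(read$seq),
       offset = as.integer(read$offset))
}

.emptyHits <- function() {
  data.frame(snp_id = character(), chrom = character(), start = integer(),
             strand = character(), cigar = character(), raw_ed = integer(),
             score = numeric(), stage = character(), clip_left = integer(),
             clip_right = integer(), stringsAsFactors = FALSE)
}

.orderHits <- function(hits, g) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(match(hits$chrom, seqNames(g)), hits$start,
               match(hits$strand, c("+", "-")))
  hits[ord, , drop = FALSE]
}

# Candidate placements for one oriented read from pigeonhole seeding:
# the read is split into maxMismatches+1 contiguous segments; any placement
# within the Hamming budget must contain at least one exact segment
# (segments forced to mismatch by N/placeholder each consume one unit of
# budget, preserving the argument). The length-seedLen prefix of each
# clean segment is looked up in the index. Returns a data.frame of implied
# (chrom, start), an empty data.frame when seeding proves no placement
# exists, or NULL when the read cannot be seeded (fall back to brute force).
.pigeonholeCandidates <- function(rs, g, chroms, cfg) {
  if (!isIndexed(g)) stop("genome has no seed index; call buildSeedIndex()")
  m <- nchar(rs)
  k <- g@seedLen
  s <- cfg@maxMismatches + 1L
  if (m < k * s) return(NULL)
  bounds <- floor(seq(0, m, length.out = s + 1L))
  q <- as.integer(bounds[-(s + 1L)])            # 0-based segment starts
  segs <- substring(rs, q + 1L, q + k)
  usable <- !grepl("[N?]", segs)
  if (!any(usable)) return(NULL)
  lens <- seqLengths(g)
  parts <- list()
  for (i in which(usable)) {
    occ <- seedLookup(g, segs[i])
    if (!nrow(occ)) next
    occ <- occ[occ$chrom %in% chroms, , drop = FALSE]
    if (!nrow(occ)) next
    start <- occ$pos - q[i]
    ok <- start >= 1L & start + m - 1L <= lens[occ$chrom]
    parts[[length(parts) + 1L]] <-
      data.frame(chrom = occ$chrom[ok], start = start[ok],
                 stringsAsFactors = FALSE)
  }
  if (!length(parts))
    return(data.frame(chrom = character(), start = integer(),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, parts)
  unique(cand)
}

#' Stage-1 ungapped search
#'
#' Returns exactly the set of placements, on both strands, whose Hamming
#' distance to the read is at most \code{maxMismatches}, the placeholder
#' counting as one mismatch and reference N as a mismatch. Completeness
#' before the hit cap is guaranteed: candidate placements come from
#' pigeonhole seeding over the seed index (or from a brute-force scan when
#' the read is too short to seed) and are verified by direct mismatch
#' counting. Hits are ordered deterministically (chromosome order as
#' loaded, start ascending, + before -) and then truncated to
#' \code{maxHits}.
#'
#' @param read a one-row data.frame from \code{\link{probeReads}}, or a
#'   single placeholder-read string.
#' @param g an indexed \linkS4class{ReferenceGenome}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param chroms chromosomes to search (default: all, in genome order).
#' @return data.frame of hits with columns snp_id, chrom, start, strand,
#'   cigar, raw_ed, score, stage, clip_left, clip_right.
#' @export
alignUngapped <- function(read, g, cfg = pipelineConfig(), chroms = NULL) {
  r <- .normRead(read)
  m <- nchar(r$seq)
  if (is.null(chroms)) chroms <- seqNames(g)
  oriented <- c("+" = r$seq, "-" = revComp(r$seq))
  rows <- list()
  for (strand in c("+", "-")) {
    rs <- oriented[[strand]]
    cand <- .pigeonholeCandidates(rs, g, chroms, cfg)
    for (chrom in chroms) {
      seq <- g@sequences[[chrom]]
      if (is.null(cand)) {
        sc <- C_scan_hamming(seq, rs, cfg@maxMismatches)
        starts <- sc$start
        cnt <- sc$mismatches
      } else {
        starts <- cand$start[cand$chrom == chrom]
        if (!length(starts)) next
        cnt <- C_mismatch_counts(seq, rs, starts, cfg@maxMismatches)
        keep <- !is.na(cnt) & cnt <= cfg@maxMismatches
        starts <- starts[keep]
        cnt <- cnt[keep]
      }
      if (!length(starts)) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = r$snp_id, chrom = chrom, start = as.integer(starts),
        strand = strand, cigar = paste0(m, "M"), raw_ed = as.integer(cnt),
        score = NA_real_, stage = "1-ungapped", clip_left = 0L,
        clip_right = 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyHits())
  hits <- .orderHits(do.call(rbind, rows), g)
  utils::head(hits, cfg@maxHits)
}

#' Stage-1 gapped rescue
#'
#' For reads without ungapped hits: each seeded candidate placement is
#' re-aligned semi-globally (the read end-to-end, free reference ends)
#' against a reference window extended by \code{gapMargin} on both sides,
#' under unit edit costs. A placement is reported when its mismatch count
#' (placeholder included) stays within \code{maxMismatches} and its total
#' gapped bases within \code{gapMargin}; the CIGAR reflects the DP
#' traceback.
#'
#' @inheritParams alignUngapped
#' @return data.frame of hits (stage \code{"1-gapped"}).
#' @export
alignGapped <- function(read, g, cfg = pipelineConfig(), chroms = NULL) {
  r <- .normRead(read)
  m <- nchar(r$seq)
  if (is.null(chroms)) chroms <- seqNames(g)
  margin <- cfg@gapMargin
  lens <- seqLengths(g)
  rows <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") r$seq else revComp(r$seq)
    cand <- .pigeonholeCandidates(rs, g, chroms, cfg)
    if (is.null(cand)) {
      # unseedable read: try every placement (small references only)
      cand <- do.call(rbind, lapply(chroms, function(ch) {
        n <- max(1L, lens[[ch]] - m + 1L)
        data.frame(chrom = ch, start = seq_len(n), stringsAsFactors = FALSE)
      }))
    }
    if (!nrow(cand)) next
    for (i in seq_len(nrow(cand))) {
      chrom <- cand$chrom[i]
      winStart <- max(1L, cand$start[i] - margin)
      winEnd <- min(lens[[chrom]], cand$start[i] + m - 1L + margin)
      if (winEnd < winStart) next
      res <- C_glocal_align(rs, substr(g@sequences[[chrom]], winStart, winEnd))
      gaps <- res$insertions + res$deletions
      if (res$mismatches > cfg@maxMismatches || gaps > margin) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = r$snp_id, chrom = chrom,
        start = winStart + res$ref_start - 1L, strand = strand,
        cigar = res$cigar,
        raw_ed = res$mismatches + res$insertions + res$deletions,
        score = NA_real_, stage = "1-gapped", clip_left = 0L,
        clip_right = 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyHits())
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[c("chrom", "start", "strand", "cigar")]), ,
               drop = FALSE]
  hits <- .orderHits(hits, g)
  utils::head(hits, cfg@maxHits)
}

#' Run stage 1
#'
#' The ungapped search; when it finds nothing and
#' \code{enableGappedStage1} is set, the gapped rescue.
#'
#' @inheritParams alignUngapped
#' @return data.frame of hits with the stage field set.
#' @export
alignStage1 <- function(read, g, cfg = pipelineConfig(), chroms = NULL) {
  hits <- alignUngapped(read, g, cfg, chroms)
  if (nrow(hits) == 0L && cfg@enableGappedStage1)
    hits <- alignGapped(read, g, cfg, chroms)
  hits
}
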