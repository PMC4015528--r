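# Stage 2: sensitive Smith-Waterman rescue for reads unmapped or
# ambiguous after stage 1.

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under
#' score = match * matches - mismatch * mismatches - (open + extend*(g-1))
#' per length-g gap. The placeholder (and N on either side) scores as a
#' mismatch against every base. Traceback is deterministic; the score is
#' never negative (an empty alignment scores 0).
#'
#' @param read,refWindow sequences (read may carry the placeholder).
#' @param cfg a \linkS4class{PipelineConfig} supplying the score scheme
#'   and the gapless flag.
#' @return list with score, cigar (M/I/D over the aligned region only),
#'   readSpan and refSpan (1-based inclusive), and the operation counts
#'   matches, mismatches, insertions, deletions.
#' @examples
#' smithWaterman("ACGT", "ACGT")$score  # 40
#' @export
smithWaterman <- function(read, refWindow, cfg = pipelineConfig()) {
  res <- C_sw_align(toupper(read), toupper(refWindow), cfg@swMatch,
                    cfg@swMismatch, cfg@swGapOpen, cfg@swGapExtend,
                    cfg@gaplessStage2)
  list(score = res$score, cigar = res$cigar,
       readSpan = c(res$read_start, res$read_end),
       refSpan = c(res$ref_start, res$ref_end),
       matches = res$matches, mismatches = res$mismatches,
       insertions = res$insertions, deletions = res$deletions)
}

#' Stage-2 rescue alignment
#'
#' Candidate reference windows are anchored by exact seed hits of the
#' read's k-mers on both strands (falling back to a sliding window scan
#' when no seed anchors at all) and scored by Smith-Waterman. No hit cap
#' is imposed at this stage. A local alignment is kept only when it covers
#' the placeholder position (otherwise the allele cannot be verified and
#' the SNP coordinate is undefined) and reaches
#' \code{swMinScoreFrac * match * read length}. Clipped read ends are
#' recorded as clip_left/clip_right and excluded from the edit distance.
#'
#' @inheritParams alignUngapped
#' @return data.frame of hits (stage \code{"2"}) with SW scores.
#' @export
alignStage2 <- function(read, g, cfg = pipelineConfig(), chroms = NULL) {
  r <- .normRead(read)
  m <- nchar(r$seq)
  if (is.null(chroms)) chroms <- seqNames(g)
  if (!isIndexed(g)) stop("genome has no seed index; call buildSeedIndex()")
  k <- g@seedLen
  margin <- cfg@gapMargin
  lens <- seqLengths(g)
  minScore <- ceiling(cfg@swMinScoreFrac * cfg@swMatch * m)

  candFor <- function(rs) {
    if (m < k) return(NULL)
    q <- unique(c(seq.int(0L, m - k, by = k), m - k))
    segs <- substring(rs, q + 1L, q + k)
    usable <- !grepl("[N?]", segs)
    if (!any(usable)) return(NULL)
    parts <- list()
    for (i in which(usable)) {
      occ <- seedLookup(g, segs[i])
      if (!nrow(occ)) next
      occ <- occ[occ$chrom %in% chroms, , drop = FALSE]
      if (!nrow(occ)) next
      parts[[length(parts) + 1L]] <-
        data.frame(chrom = occ$chrom, start = occ$pos - q[i],
                   stringsAsFactors = FALSE)
    }
    if (!length(parts))
      return(data.frame(chrom = character(), start = integer(),
                        stringsAsFactors = FALSE))
    unique(do.call(rbind, parts))
  }

  oriented <- c("+" = r$seq, "-" = revComp(r$seq))
  cands <- lapply(oriented, candFor)
  if (all(vapply(cands, function(x) is.null(x) || nrow(x) == 0L, TRUE))) {
    # no anchor anywhere: sliding-window scan (small references only)
    step <- max(1L, margin)
    full <- do.call(rbind, lapply(chroms, function(ch) {
      n <- max(1L, lens[[ch]] - m + 1L)
      data.frame(chrom = ch, start = seq.int(1L, n, by = step),
                 stringsAsFactors = FALSE)
    }))
    cands <- list("+" = full, "-" = full)
  }

  rows <- list()
  for (strand in c("+", "-")) {
    rs <- oriented[[strand]]
    cand <- cands[[strand]]
    if (is.null(cand) || !nrow(cand)) next
    p1 <- if (strand == "+") r$offset + 1L else m - r$offset  # 1-based in rs
    for (i in seq_len(nrow(cand))) {
      chrom <- cand$chrom[i]
      winStart <- max(1L, cand$start[i] - margin)
      winEnd <- min(lens[[chrom]], cand$start[i] + m - 1L + margin)
      if (winEnd < winStart) next
      res <- C_sw_align(rs, substr(g@sequences[[chrom]], winStart, winEnd),
                        cfg@swMatch, cfg@swMismatch, cfg@swGapOpen,
                        cfg@swGapExtend, cfg@gaplessStage2)
      if (res$score < minScore) next
      if (p1 < res$read_start || p1 > res$read_end) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = r$snp_id, chrom = chrom,
        start = winStart + res$ref_start - 1L, strand = strand,
        cigar = res$cigar,
        raw_ed = res$mismatches + res$insertions + res$deletions,
        score = as.numeric(res$score), stage = "2",
        clip_left = res$read_start - 1L, clip_right = m - res$read_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyHits())
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[c("chrom", "start", "strand", "cigar")]), ,
               drop = FALSE]
  .orderHits(hits, g)
}
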