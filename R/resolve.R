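# Stage 3: allele-consistency filtering, edit-distance correction,
# best-hit selection with ambiguity semantics, and absolute SNP position
# computation from CIGAR and strand.

.parseCigar <- function(cigar) {
  m <- gregexpr("\\d+[MID]", cigar)[[1]]
  if (m[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  list(len = as.integer(sub("[MID]", "", toks)),
       op = substring(toks, nchar(toks)))
}

#' Resolve the SNP's reference coordinate from a hit
#'
#' Walks the CIGAR from the hit's leftmost reference base. The effective
#' read offset is \code{snpOffset} on the + strand and
#' \code{readLen - 1 - snpOffset} on the - strand (the aligned read is the
#' reverse complement there); stage-2 clips shift it by \code{clipLeft}.
#' M consumes read and reference, I read only, D reference only.
#'
#' @param start 1-based leftmost reference base consumed by the alignment.
#' @param cigar CIGAR over M/I/D for the aligned region.
#' @param strand \code{"+"} or \code{"-"}.
#' @param readLen full read length (placeholder included).
#' @param snpOffset 0-based placeholder offset in the probe read.
#' @param clipLeft,clipRight unaligned read bases at either end of the
#'   aligned (oriented) read.
#' @return The 1-based reference position of the SNP base, or
#'   \code{NA_integer_} with attribute \code{reason} set to
#'   \code{"in_insertion"} (placeholder falls inside an I run) or
#'   \code{"not_covered"} (placeholder clipped off the local alignment).
#' @examples
#' snpRefPosition(101, "53M", "+", 53, 26)        # 127
#' snpRefPosition(101, "10M2D43M", "+", 53, 26)   # 129
#' @export
snpRefPosition <- function(start, cigar, strand, readLen, snpOffset,
                           clipLeft = 0L, clipRight = 0L) {
  cg <- .parseCigar(cigar)
  alignedRead <- sum(cg$len[cg$op %in% c("M", "I")])
  if (alignedRead + clipLeft + clipRight != readLen)
    stop("CIGAR ", cigar, " inconsistent with read length ", readLen)
  o <- if (strand == "+") snpOffset else readLen - 1L - snpOffset
  o <- o - clipLeft
  if (o < 0L || o >= alignedRead) {
    out <- NA_integer_
    attr(out, "reason") <- "not_covered"
    return(out)
  }
  rd <- 0L
  ref <- as.integer(start)
  for (i in seq_along(cg$op)) {
    L <- cg$len[i]
    if (cg$op[i] == "M") {
      if (o < rd + L) return(ref + (o - rd))
      rd <- rd + L
      ref <- ref + L
    } else if (cg$op[i] == "I") {
      if (o < rd + L) {
        out <- NA_integer_
        attr(out, "reason") <- "in_insertion"
        return(out)
      }
      rd <- rd + L
    } else {
      ref <- ref + L
    }
  }
  stop("CIGAR walk exhausted before reaching the placeholder")
}

#' Allele-consistency filter and edit-distance correction
#'
#' A placement is a false positive when the reference base under the
#' placeholder matches none of the SNP's alleles: on the + strand the base
#' itself is checked against the allele set, on the - strand its
#' complement (the aligned read is the reverse complement of the probe).
#' Accepted hits get \code{corrected_ed = raw_ed - 1}, removing the one
#' guaranteed placeholder mismatch. Rejections carry a reason code:
#' \code{allele_mismatch}, \code{in_insertion}, \code{not_covered} or
#' \code{ref_N} (reference N, allele unverifiable).
#'
#' @param hits data.frame of hits for one SNP.
#' @param probe a length-1 \linkS4class{SnpProbeSet}.
#' @param g the \linkS4class{ReferenceGenome}.
#' @return list with elements \code{accepted} (hits plus snp_pos and
#'   corrected_ed columns) and \code{rejected} (hits plus a reason column).
#' @export
classifyHits <- function(hits, probe, g) {
  stopifnot(length(probe) == 1L)
  alleles <- probe@alleles[[1]]
  readLen <- probeWidth(probe)
  off <- nchar(probe@leftFlank)
  n <- nrow(hits)
  snp_pos <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- snpRefPosition(hits$start[i], hits$cigar[i], hits$strand[i],
                        readLen, off, hits$clip_left[i], hits$clip_right[i])
    if (is.na(p)) {
      reason[i] <- attr(p, "reason")
      next
    }
    b <- substr(g@sequences[[hits$chrom[i]]], p, p)
    if (b == "N") {
      reason[i] <- "ref_N"
      next
    }
    checked <- if (hits$strand[i] == "+") b else chartr("ACGT", "TGCA", b)
    if (checked %in% alleles) snp_pos[i] <- p else reason[i] <- "allele_mismatch"
  }
  ok <- !is.na(snp_pos)
  accepted <- hits[ok, , drop = FALSE]
  accepted$snp_pos <- snp_pos[ok]
  accepted$corrected_ed <- accepted$raw_ed - 1L
  rejected <- hits[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  list(accepted = accepted, rejected = rejected)
}

#' Best-hit selection with ambiguity semantics
#'
#' Stage-1 hits are ranked by corrected edit distance (ascending), stage-2
#' hits by Smith-Waterman score (descending). A shared top key means the
#' SNP cannot be placed: status \code{ambiguous}, MAPQ 0. A sole hit gets
#' MAPQ 60; otherwise the gap between best and second-best key is mapped
#' onto 0-60: \code{min(60, round(60*(k2-k1)/maxMismatches))} at stage 1
#' and \code{min(60, round(60*(S1-S2)/S1))} at stage 2 - a monotone
#' surrogate for an aligner-reported mapping quality preserving the
#' semantics the pipeline relies on (tie implies ambiguous, bigger gap
#' implies more confident).
#'
#' @param accepted allele-accepted hits for one SNP (from
#'   \code{\link{classifyHits}}).
#' @param stage \code{"1"} or \code{"2"}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return list with status (\code{"unique"}, \code{"ambiguous"} or
#'   \code{"none"}), hit (the best row, or NULL) and mapq.
#' @export
selectBest <- function(accepted, stage = c("1", "2"), cfg = pipelineConfig()) {
  stage <- match.arg(stage)
  n <- nrow(accepted)
  if (n == 0L) return(list(status = "none", hit = NULL, mapq = NA_integer_))
  key <- if (stage == "1") as.numeric(accepted$corrected_ed)
         else -as.numeric(accepted$score)
  ord <- order(key, accepted$chrom, accepted$start, accepted$strand)
  a <- accepted[ord, , drop = FALSE]
  key <- key[ord]
  if (n >= 2L && key[1] == key[2])
    return(list(status = "ambiguous", hit = a[1, , drop = FALSE], mapq = 0L))
  mapq <- if (n == 1L) {
    60L
  } else if (stage == "1") {
    min(60L, as.integer(round(60 * (a$corrected_ed[2] - a$corrected_ed[1]) /
                                cfg@maxMismatches)))
  } else {
    min(60L, as.integer(round(60 * (a$score[1] - a$score[2]) / a$score[1])))
  }
  list(status = "unique", hit = a[1, , drop = FALSE], mapq = mapq)
}
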