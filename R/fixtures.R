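# Synthetic fixtures with known ground truth: random genomes, optional
# duplicated decoy segments, and probes cut from the genome with a
# central allele construct and controlled flank mutations.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random reference genome
#'
#' Uniform random A/C/G/T chromosomes, reproducible under \code{seed}.
#' \code{duplications} copies windows verbatim elsewhere to create exact
#' decoy segments for ambiguity fixtures.
#'
#' @param nChroms number of chromosomes.
#' @param lengths chromosome lengths (recycled to \code{nChroms}).
#' @param seed RNG seed (the caller's RNG state is restored).
#' @param chromNames chromosome names.
#' @param duplications optional data.frame with columns chrom, start, end,
#'   to: the window [start, end] of chrom is copied to position to of the
#'   same chromosome.
#' @param fastaPath optional path; when given the genome is also written
#'   as FASTA.
#' @return An unindexed \linkS4class{ReferenceGenome}.
#' @examples
#' g <- generateGenome(lengths = 1000, seed = 7)
#' @export
generateGenome <- function(nChroms = 1, lengths = 10000, seed = 1,
                           chromNames = paste0("chr", seq_len(nChroms)),
                           duplications = NULL, fastaPath = NULL) {
  lengths <- rep_len(as.integer(lengths), nChroms)
  seqs <- .withSeed(seed, {
    vapply(lengths, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), "")
  })
  names(seqs) <- chromNames
  if (!is.null(duplications)) {
    for (i in seq_len(nrow(duplications))) {
      d <- duplications[i, ]
      win <- substr(seqs[[d$chrom]], d$start, d$end)
      substr(seqs[[d$chrom]], d$to, d$to + nchar(win) - 1L) <- win
    }
  }
  g <- referenceGenome(seqs)
  if (!is.null(fastaPath)) writeReference(g, fastaPath)
  g
}

.bruteHitCount <- function(g, readSeq, maxMm) {
  total <- 0L
  rc <- revComp(readSeq)
  for (chrom in seqNames(g)) {
    s <- g@sequences[[chrom]]
    total <- total + length(C_scan_hamming(s, readSeq, maxMm)$start) +
      length(C_scan_hamming(s, rc, maxMm)$start)
  }
  total
}

.mutateFlanks <- function(lf, rf, mutation, nMismatches, indelLen, indelType) {
  if (mutation %in% c("exact", "allele_inconsistent"))
    return(list(lf = lf, rf = rf))
  read <- c(strsplit(lf, "", fixed = TRUE)[[1]], NA,
            strsplit(rf, "", fixed = TRUE)[[1]])
  center <- nchar(lf) + 1L
  if (mutation == "mismatches") {
    # interior positions only: keeps the mutation count identifiable in
    # the corrected edit distance (no end effects in local alignment)
    pool <- setdiff(3:(length(read) - 2L), center)
    at <- sample(pool, nMismatches)
    for (p in at) read[p] <- sample(setdiff(DNA_BASES, read[p]), 1L)
    lf2 <- paste(read[seq_len(center - 1L)], collapse = "")
    rf2 <- paste(read[(center + 1L):length(read)], collapse = "")
    return(list(lf = lf2, rf = rf2))
  }
  # indel: applied to the interior of one flank, away from the read ends
  # and the placeholder so the operation is visible in the CIGAR
  side <- sample(c("L", "R"), 1L)
  fl <- if (side == "L") lf else rf
  lo <- 5L
  hi <- nchar(fl) - 4L - if (indelType == "del") indelLen else 0L
  if (hi < lo) stop("flank too short for the requested indel")
  at <- sample(lo:hi, 1L)
  if (indelType == "del") {
    fl2 <- paste0(substr(fl, 1L, at - 1L),
                  substr(fl, at + indelLen, nchar(fl)))
  } else {
    fl2 <- paste0(substr(fl, 1L, at - 1L),
                  paste(sample(DNA_BASES, indelLen, replace = TRUE),
                        collapse = ""),
                  substr(fl, at, nchar(fl)))
  }
  if (side == "L") list(lf = fl2, rf = rf) else list(lf = lf, rf = fl2)
}

#' Plant probes with known ground truth
#'
#' Cuts \code{n} probes from random genome positions. The centre base
#' becomes one allele; for consistent probes the second allele is drawn
#' different from the reference base, for allele-inconsistent probes both
#' alleles differ from it. Mutations are applied to the flanks only,
#' never at the placeholder. Every probe's context is verified by brute
#' force at generation time: consistent/inconsistent probes must have
#' exactly one placement within the Hamming budget (unless
#' \code{requireUnique = FALSE}, e.g. for duplicated-segment fixtures,
#' where two or more placements make the expected status ambiguous);
#' indel probes must have no ungapped placement at all and a unique
#' unmutated context.
#'
#' @param g a \linkS4class{ReferenceGenome}.
#' @param n number of probes.
#' @param flankLen flank length (default 26, a typical probe half-width).
#' @param mutation one of \code{"exact"}, \code{"mismatches"},
#'   \code{"indel"}, \code{"allele_inconsistent"}.
#' @param nMismatches flank mismatches for \code{mutation = "mismatches"}.
#' @param indelLen,indelType indel length and type (\code{"del"} removes
#'   bases from the read, giving a D in the CIGAR; \code{"ins"} adds
#'   bases, giving an I).
#' @param declared \code{"truth"} declares the planted chromosome and SNP
#'   position; \code{"blank"} models vendor-unmapped probes.
#' @param region optional list(chrom, start, end) restricting planted
#'   reads to lie inside that window.
#' @param requireUnique resample until the planted context is unique
#'   within the Hamming budget.
#' @param seed RNG seed.
#' @param cfg \linkS4class{PipelineConfig} supplying the Hamming budget
#'   used for the generation-time checks.
#' @param idPrefix identifier prefix.
#' @param maxTries resampling attempts per probe before giving up.
#' @return list with \code{probes} (a \linkS4class{SnpProbeSet}) and
#'   \code{truth} (data.frame: snp_id, chrom, planted_pos, read_start,
#'   alleles, mutation, n_mut, expected_status, expected_corrected).
#' @export
plantProbes <- function(g, n, flankLen = 26,
                        mutation = c("exact", "mismatches", "indel",
                                     "allele_inconsistent"),
                        nMismatches = 0, indelLen = 1,
                        indelType = c("del", "ins"),
                        declared = c("truth", "blank"),
                        region = NULL, requireUnique = TRUE,
                        seed = 1, cfg = pipelineConfig(),
                        idPrefix = "snp", maxTries = 50) {
  mutation <- match.arg(mutation)
  indelType <- match.arg(indelType)
  declared <- match.arg(declared)
  lens <- seqLengths(g)
  if (is.null(region)) {
    avail <- pmax(0L, lens - 2L * flankLen)
    if (sum(avail) < n) stop("genome too small for ", n, " probes")
  }
  .withSeed(seed, {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(maxTries)) {
        if (is.null(region)) {
          chrom <- sample(seqNames(g), 1L, prob = pmax(0, lens - 2 * flankLen))
          center <- sample((flankLen + 1L):(lens[[chrom]] - flankLen), 1L)
        } else {
          chrom <- region$chrom
          lo <- region$start + flankLen
          hi <- region$end - flankLen
          if (hi < lo) stop("region too small for flankLen ", flankLen)
          center <- sample(lo:hi, 1L)
        }
        s <- g@sequences[[chrom]]
        refBase <- substr(s, center, center)
        if (refBase == "N") next
        lf <- substr(s, center - flankLen, center - 1L)
        rf <- substr(s, center + 1L, center + flankLen)
        if (grepl("N", paste0(lf, rf), fixed = TRUE)) next
        alleles <- if (mutation == "allele_inconsistent") {
          sample(setdiff(DNA_BASES, refBase), 2L)
        } else {
          c(refBase, sample(setdiff(DNA_BASES, refBase), 1L))
        }
        mut <- .mutateFlanks(lf, rf, mutation, nMismatches, indelLen,
                             indelType)
        readSeq <- paste0(mut$lf, PLACEHOLDER, mut$rf)
        contextSeq <- paste0(lf, PLACEHOLDER, rf)
        nhits <- .bruteHitCount(g, readSeq, cfg@maxMismatches)
        if (mutation == "indel" ||
            (mutation == "mismatches" && nMismatches > cfg@maxMismatches)) {
          # beyond the ungapped budget: resolvable only by the gapped or
          # Smith-Waterman stages, anchored at a unique unmutated context
          if (nhits != 0L) next
          if (.bruteHitCount(g, contextSeq, cfg@maxMismatches) != 1L) next
          status <- "unique"
        } else if (requireUnique) {
          if (nhits != 1L) next
          status <- if (mutation == "allele_inconsistent") "allele_filtered"
                    else "unique"
        } else {
          if (nhits < 2L) next
          status <- "ambiguous"
        }
        expCorr <- switch(mutation, exact = 0L,
                          mismatches = as.integer(nMismatches),
                          indel = as.integer(indelLen),
                          allele_inconsistent = NA_integer_)
        recs[[i]] <- list(
          snp_id = sprintf("%s%04d", idPrefix, i), chrom = chrom,
          planted_pos = center, read_start = center - flankLen,
          lf = mut$lf, rf = mut$rf,
          alleles = paste(alleles, collapse = "/"),
          mutation = mutation,
          n_mut = switch(mutation, mismatches = as.integer(nMismatches),
                         indel = as.integer(indelLen), 0L),
          expected_status = status, expected_corrected = expCorr)
        done <- TRUE
        break
      }
      if (!done)
        stop("could not place probe ", i, " after ", maxTries, " tries")
    }
    truth <- do.call(rbind, lapply(recs, function(r)
      data.frame(r[setdiff(names(r), c("lf", "rf"))],
                 stringsAsFactors = FALSE)))
    probes <- SnpProbeSet(
      snpId = truth$snp_id,
      leftFlank = vapply(recs, `[[`, "", "lf"),
      rightFlank = vapply(recs, `[[`, "", "rf"),
      alleles = strsplit(truth$alleles, "/", fixed = TRUE),
      declaredChrom = if (declared == "truth") truth$chrom else NA_character_,
      declaredPos = if (declared == "truth") truth$planted_pos else NA_integer_)
    list(probes = probes, truth = truth)
  })
}
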