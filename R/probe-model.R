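#' Parse bracketed-allele probe strings
#'
#' A SNP probe is written as the flanking sequence with the allele group in
#' brackets, e.g. \code{"TT[A/G]CC"} (manifest dialect) or \code{"TT[AG]CC"}.
#' Exactly one bracket group of 2-4 distinct A/C/G/T bases is required;
#' input case is normalised to uppercase.
#'
#' @param s character vector of probe strings.
#' @param snpId identifiers (default \code{probe1}, \code{probe2}, ...).
#' @param declaredChrom,declaredPos optional vendor-declared coordinates.
#' @return A \linkS4class{SnpProbeSet}.
#' @examples
#' p <- parseProbeString("GCACTCTCACATGGATTAGGGAATTA[CG]ATGCAGACCTCCTGCACAACTGCCC")
#' alleleList(p)[[1]]
#' @export
parseProbeString <- function(s, snpId = paste0("probe", seq_along(s)),
                             declaredChrom = NA_character_,
                             declaredPos = NA_integer_) {
  s <- toupper(as.character(s))
  m <- gregexpr("\\[[^][]*\\]", s)
  left <- right <- character(length(s))
  alleles <- vector("list", length(s))
  for (i in seq_along(s)) {
    hits <- m[[i]]
    if (hits[1] == -1L || length(hits) != 1L)
      stop("probe string must contain exactly one [..] allele group: ", s[i])
    st <- hits[1]
    len <- attr(hits, "match.length")[1]
    inner <- substr(s[i], st + 1L, st + len - 2L)
    a <- strsplit(gsub("/", "", inner, fixed = TRUE), "", fixed = TRUE)[[1]]
    if (length(a) < 2 || length(a) > 4 || anyDuplicated(a) ||
        !all(a %in% DNA_BASES))
      stop("allele group must hold 2-4 distinct A/C/G/T bases: [", inner, "]")
    left[i] <- substr(s[i], 1L, st - 1L)
    right[i] <- substr(s[i], st + len, nchar(s[i]))
    alleles[[i]] <- a
  }
  SnpProbeSet(snpId, left, right, alleles, declaredChrom, declaredPos)
}

#' Render probes back to bracket form
#'
#' Inverse of \code{\link{parseProbeString}} on canonical uppercase input.
#'
#' @param x a \linkS4class{SnpProbeSet}.
#' @param sep separator between alleles inside the brackets (\code{""} or
#'   \code{"/"}).
#' @return character vector of probe strings.
#' @export
probeString <- function(x, sep = "") {
  paste0(x@leftFlank, "[",
         vapply(x@alleles, paste, "", collapse = sep), "]",
         x@rightFlank)
}

#' Collapse probes to placeholder reads
#'
#' Each SNP is represented by a single read in which the allele group is
#' replaced by one placeholder character that aligns as a mismatch against
#' every reference base. The read is
#' \code{left_flank + placeholder + right_flank}; the 0-based placeholder
#' offset equals the left flank length.
#'
#' @param x a \linkS4class{SnpProbeSet}.
#' @return data.frame with columns snp_id, seq (placeholder read) and
#'   offset (0-based placeholder index).
#' @examples
#' probeReads(parseProbeString("A[C/G]T"))
#' @export
probeReads <- function(x) {
  if (length(x) == 0L)
    return(data.frame(snp_id = character(), seq = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  data.frame(snp_id = x@snpId,
             seq = paste0(x@leftFlank, PLACEHOLDER, x@rightFlank),
             offset = nchar(x@leftFlank),
             stringsAsFactors = FALSE)
}

#' Reverse-complement sequences carrying a placeholder
#'
#' Watson-Crick complement plus reversal over the alphabet
#' A,C,G,T,N and the placeholder, which maps to itself. A placeholder
#' 0-based offset o maps to \code{length - 1 - o}.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revComp("AA?T")  # "A?TT"
#' @export
revComp <- function(x) {
  bad <- grepl("[^ACGTN?]", x)
  if (any(bad)) stop("illegal character in sequence: ", x[bad][1])
  x <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' Reverse-complement a probe set
#'
#' Swaps and reverse-complements the flanks and complements the allele
#' set, i.e. re-expresses each probe on the opposite strand. Mapping a
#' reverse-complemented probe yields the identical SNP position, status
#' and corrected edit distance, with the reported strand flipped.
#'
#' @param x a \linkS4class{SnpProbeSet}.
#' @return A \linkS4class{SnpProbeSet}.
#' @export
revCompProbes <- function(x) {
  new("SnpProbeSet",
      snpId = x@snpId,
      leftFlank = revComp(x@rightFlank),
      rightFlank = revComp(x@leftFlank),
      alleles = lapply(x@alleles, function(a) unname(chartr("ACGT", "TGCA", a))),
      declaredChrom = x@declaredChrom,
      declaredPos = x@declaredPos)
}

#' Read an Illumina-style manifest
#'
#' Comma-separated manifest with an optional section preamble (lines up to
#' and including \code{[Assay]}) before the header row. Required columns:
#' a SNP name column (\code{Name}), the allele column (\code{SNP}, e.g.
#' \code{"[A/G]"}), chromosome (\code{Chr}), 1-based position
#' (\code{MapInfo}) and a genomic-sequence column containing the bracket
#' construct. Rows with position 0/empty chromosome become vendor-unmapped
#' probes (absent declared coordinates). Rows whose sequence cell cannot
#' be parsed are skipped with a warning.
#'
#' @param path manifest file path.
#' @param seqColumn name of the genomic-sequence column; the default
#'   \code{"TopGenomicSeq"} is the Illumina column holding the bracket
#'   construct in top-strand orientation. \code{"SourceSeq"} is accepted
#'   alternatively via this argument.
#' @param nameColumn,alleleColumn,chromColumn,posColumn column names.
#' @return A \linkS4class{SnpProbeSet}.
#' @export
parseManifest <- function(path, seqColumn = "TopGenomicSeq",
                          nameColumn = "Name", alleleColumn = "SNP",
                          chromColumn = "Chr", posColumn = "MapInfo") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty manifest: ", path)
  start <- 1L
  assay <- which(trimws(lines) == "[Assay]")
  if (length(assay)) start <- assay[1] + 1L
  df <- utils::read.csv(text = paste(lines[start:length(lines)], collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(nameColumn, alleleColumn, chromColumn, posColumn, seqColumn)) {
    if (!col %in% names(df))
      stop("manifest is missing required column: ", col)
  }
  keep <- rep(TRUE, nrow(df))
  left <- right <- character(nrow(df))
  alleles <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- tryCatch(parseProbeString(df[[seqColumn]][i]), error = function(e) NULL)
    if (is.null(p)) {
      warning("skipping manifest row ", i, " (", df[[nameColumn]][i],
              "): malformed sequence cell")
      keep[i] <- FALSE
      next
    }
    left[i] <- leftFlank(p)
    right[i] <- rightFlank(p)
    alleles[[i]] <- alleleList(p)[[1]]
  }
  chrom <- trimws(as.character(df[[chromColumn]]))
  pos <- suppressWarnings(as.integer(df[[posColumn]]))
  unplaced <- is.na(pos) | pos == 0L | chrom == "" | chrom == "0"
  chrom[unplaced] <- NA_character_
  pos[unplaced] <- NA_integer_
  SnpProbeSet(df[[nameColumn]][keep], left[keep], right[keep],
              alleles[keep], chrom[keep], pos[keep])
}

#' Write probe FASTA and info files
#'
#' Writes the two-file probe representation: a FASTA of placeholder reads
#' keyed by snp_id (the placeholder is written as \code{N}; the info
#' file's snp_offset column disambiguates it from genuine flank Ns) and a
#' tab-delimited info file with a commented header and columns snp_id,
#' chrom, pos, alleles, snp_offset. Absent values are written as ".".
#' Round-trips losslessly through \code{\link{readProbeInputs}}.
#'
#' @param x a \linkS4class{SnpProbeSet}.
#' @param fastaPath,infoPath output paths.
#' @return invisibly, \code{x}.
#' @export
writeProbeInputs <- function(x, fastaPath, infoPath) {
  reads <- probeReads(x)
  seqs <- Biostrings::DNAStringSet(gsub("?", "N", reads$seq, fixed = TRUE))
  names(seqs) <- reads$snp_id
  tryCatch(Biostrings::writeXStringSet(seqs, fastaPath),
           error = function(e) stop("cannot write FASTA ", fastaPath, ": ",
                                    conditionMessage(e)))
  info <- data.frame(
    snp_id = x@snpId,
    chrom = ifelse(is.na(x@declaredChrom), ".", x@declaredChrom),
    pos = ifelse(is.na(x@declaredPos), ".", as.character(x@declaredPos)),
    alleles = vapply(x@alleles, paste, "", collapse = "/"),
    snp_offset = reads$offset,
    stringsAsFactors = FALSE)
  con <- tryCatch(file(infoPath, "w"),
                  error = function(e) stop("cannot open info file ", infoPath,
                                           ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines("#snp_id\tchrom\tpos\talleles\tsnp_offset", con)
  utils::write.table(info, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read probe FASTA and info files
#'
#' Inverse of \code{\link{writeProbeInputs}}.
#'
#' @param fastaPath,infoPath input paths.
#' @return A \linkS4class{SnpProbeSet}.
#' @export
readProbeInputs <- function(fastaPath, infoPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  info <- utils::read.table(infoPath, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE,
                            col.names = c("snp_id", "chrom", "pos",
                                          "alleles", "snp_offset"),
                            colClasses = c("character", "character",
                                           "character", "character", "integer"))
  if (nrow(info) == 0L)
    return(SnpProbeSet(character(), character(), character(), list()))
  idx <- match(info$snp_id, ids)
  if (anyNA(idx)) stop("info file names SNPs absent from FASTA: ",
                       info$snp_id[is.na(idx)][1])
  seqc <- toupper(as.character(seqs[idx]))
  off <- info$snp_offset
  left <- substr(seqc, 1L, off)
  right <- substr(seqc, off + 2L, nchar(seqc))
  chrom <- ifelse(info$chrom == ".", NA_character_, info$chrom)
  pos <- suppressWarnings(as.integer(ifelse(info$pos == ".", NA, info$pos)))
  SnpProbeSet(info$snp_id, left, right, strsplit(info$alleles, "/", fixed = TRUE),
              chrom, pos)
}

#' Write an Illumina-style manifest
#'
#' Emits a minimal comma-separated manifest with an \code{[Assay]} section
#' preamble and the columns \code{\link{parseManifest}} requires. Used by
#' the fixture generator; vendor-unmapped probes get Chr 0 / MapInfo 0.
#'
#' @param x a \linkS4class{SnpProbeSet}.
#' @param path output path.
#' @return invisibly, \code{x}.
#' @export
writeManifest <- function(x, path) {
  rows <- data.frame(
    IlmnID = x@snpId,
    Name = x@snpId,
    SNP = paste0("[", vapply(x@alleles, paste, "", collapse = "/"), "]"),
    Chr = ifelse(is.na(x@declaredChrom), "0", x@declaredChrom),
    MapInfo = ifelse(is.na(x@declaredPos), 0L, x@declaredPos),
    TopGenomicSeq = probeString(x, sep = "/"),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Heading]", "Descriptor File Name,synthetic", "[Assay]"), con)
  utils::write.table(rows, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(x)
}
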