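# Independent oracles. These deliberately share no code with the package:
# the scan oracle is a vectorised shift-compare in R, the alignment
# oracles are plain R dynamic programs.

oracle_revcomp <- function(s) {
  ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "?" = "?")
  paste(map[ch], collapse = "")
}

# all forward-strand placements of `readSeq` in `chromSeq` with Hamming
# distance <= maxMm ('?' and N always mismatch)
oracle_hamming_scan <- function(chromSeq, readSeq, maxMm) {
  gr <- charToRaw(chromSeq)
  rr <- charToRaw(readSeq)
  L <- length(gr)
  m <- length(rr)
  n <- L - m + 1L
  if (n < 1L) return(data.frame(start = integer(), mismatches = integer()))
  wild <- rr == charToRaw("?") | rr == charToRaw("N")
  gN <- gr == charToRaw("N")
  mm <- integer(n)
  for (j in seq_len(m)) {
    idx <- j:(j + n - 1L)
    mm <- mm + as.integer(wild[j] | gN[idx] | gr[idx] != rr[j])
  }
  keep <- mm <= maxMm
  data.frame(start = which(keep), mismatches = mm[keep])
}

# every placement on both strands across a genome, as sorted keys
oracle_all_placements <- function(g, readSeq, maxMm) {
  out <- list()
  for (chrom in seqNames(g)) {
    s <- getChromSeq(g, chrom)
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") readSeq else oracle_revcomp(readSeq)
      sc <- oracle_hamming_scan(s, rs, maxMm)
      if (nrow(sc))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = sc$start, strand = strand,
          mismatches = sc$mismatches, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# local-alignment score under linear gap cost (valid whenever the gap
# open and extend penalties are equal), row-vectorised
oracle_sw_score <- function(a, b, match = 10, mism = 15, gap = 33) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A)
  n <- length(B)
  wildA <- A %in% c("N", "?")
  wildB <- B %in% c("N", "?")
  prev <- numeric(n + 1L)
  best <- 0
  jw <- gap * seq_len(n)
  for (i in seq_len(m)) {
    s <- ifelse(!wildA[i] & !wildB & B == A[i], match, -mism)
    cand <- pmax(0, prev[seq_len(n)] + s, prev[-1L] - gap)
    cur <- c(0, cummax(cand + jw) - jw)
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# full Gotoh local alignment with traceback; returns the score and the
# operation decomposition (matches, mismatches, gap bases). Loop DP,
# independent of the compiled implementation.
oracle_sw_full <- function(a, b, match = 10, mism = 15, open = 33, ext = 33) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A)
  n <- length(B)
  NEG <- -1e9
  H <- matrix(0, m + 1L, n + 1L)
  D <- matrix(NEG, m + 1L, n + 1L)
  I <- matrix(NEG, m + 1L, n + 1L)
  sub <- function(i, j) {
    if (A[i] %in% c("N", "?") || B[j] %in% c("N", "?") || A[i] != B[j])
      -mism else match
  }
  for (i in 1:m) for (j in 1:n) {
    D[i + 1, j + 1] <- max(H[i + 1, j] - open, D[i + 1, j] - ext)
    I[i + 1, j + 1] <- max(H[i, j + 1] - open, I[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + sub(i, j), D[i + 1, j + 1],
                           I[i + 1, j + 1])
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  score <- max(H)
  nmat <- nmm <- ngap <- 0L
  if (score > 0) {
    i <- best[1] - 1L
    j <- best[2] - 1L
    state <- "H"
    repeat {
      if (state == "H") {
        if (H[i + 1, j + 1] == 0) break
        if (i > 0 && j > 0 && H[i + 1, j + 1] == H[i, j] + sub(i, j)) {
          if (sub(i, j) > 0) nmat <- nmat + 1L else nmm <- nmm + 1L
          i <- i - 1L
          j <- j - 1L
        } else if (H[i + 1, j + 1] == D[i + 1, j + 1]) {
          state <- "D"
        } else {
          state <- "I"
        }
      } else if (state == "D") {
        ngap <- ngap + 1L
        from_open <- D[i + 1, j + 1] == H[i + 1, j] - open
        j <- j - 1L
        if (from_open) state <- "H"
      } else {
        ngap <- ngap + 1L
        from_open <- I[i + 1, j + 1] == H[i, j + 1] - open
        i <- i - 1L
        if (from_open) state <- "H"
      }
    }
  }
  list(score = score, matches = nmat, mismatches = nmm, gap_bases = ngap)
}

# minimum semi-global edit cost (read end-to-end, free reference ends)
oracle_glocal_cost <- function(readSeq, window) {
  A <- strsplit(readSeq, "", fixed = TRUE)[[1]]
  B <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- length(A)
  n <- length(B)
  prev <- rep(0L, n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1] <- i
    for (j in seq_len(n)) {
      cost <- if (A[i] %in% c("N", "?") || B[j] %in% c("N", "?") ||
                  A[i] != B[j]) 1L else 0L
      cur[j + 1] <- min(prev[j] + cost, prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# recount a hit's CIGAR against the sequences: returns the operation
# decomposition implied by walking the alignment
recount_cigar <- function(readSeq, refSeq, start, cigar,
                          readFrom = 1L) {
  toks <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  len <- as.integer(sub("[MID]", "", toks))
  op <- substring(toks, nchar(toks))
  i <- readFrom
  j <- as.integer(start)
  nmat <- nmm <- nins <- ndel <- 0L
  for (t in seq_along(op)) {
    if (op[t] == "M") {
      for (u in seq_len(len[t])) {
        a <- substr(readSeq, i, i)
        b <- substr(refSeq, j, j)
        if (a %in% c("N", "?") || b == "N" || a != b) nmm <- nmm + 1L
        else nmat <- nmat + 1L
        i <- i + 1L
        j <- j + 1L
      }
    } else if (op[t] == "I") {
      nins <- nins + len[t]
      i <- i + len[t]
    } else {
      ndel <- ndel + len[t]
      j <- j + len[t]
    }
  }
  list(matches = nmat, mismatches = nmm, insertions = nins, deletions = ndel)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

cigar_op_total <- function(cigar, op) {
  toks <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  sum(as.integer(sub("[MID]", "", toks))[substring(toks, nchar(toks)) == op])
}

hit_keys <- function(h) {
  if (!nrow(h)) return(character())
  sort(paste(h$chrom, h$start, h$strand, h$raw_ed, sep = ":"))
}
oracle_keys <- function(o) {
  if (!nrow(o)) return(character())
  sort(paste(o$chrom, o$start, o$strand, o$mismatches, sep = ":"))
}
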