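cfg_all <- pipelineConfig(maxHits = 10^6)

test_that("short reads fall back to a complete brute-force scan", {
  g <- buildSeedIndex(referenceGenome(c(chr1 = "AAACTAAA")), seedLen = 4)
  h <- alignUngapped("A?T", g, cfg_all)
  # placeholder mismatch leaves distance 1 at start 3 (A=A, ?!=C, T=T)
  expect_true(any(h$chrom == "chr1" & h$start == 3 & h$strand == "+" &
                    h$raw_ed == 1))
  expect_identical(hit_keys(h),
                   oracle_keys(oracle_all_placements(g, "A?T", 4)))
  expect_true(all(h$cigar == "3M"))
})

test_that("a planted unique probe yields one forward hit at distance 1", {
  set.seed(31)
  s <- random_dna(3000)
  read <- paste0(substr(s, 1001, 1026), "?", substr(s, 1028, 1053))
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  h <- alignUngapped(read, g, cfg_all)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1001L)
  expect_equal(h$strand, "+")
  expect_equal(h$raw_ed, 1L)
  expect_equal(h$stage, "1-ungapped")
})

test_that("the mismatch budget boundary is sharp (placeholder included)", {
  set.seed(32)
  s <- random_dna(3000)
  read <- paste0(substr(s, 1001, 1026), "?", substr(s, 1028, 1053))
  # 4 flank mismatches + placeholder = 5 > 4: no hit
  r5 <- read
  for (p in c(3, 8, 40, 50))
    substr(r5, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(r5, p, p))[1]
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  expect_equal(nrow(alignUngapped(r5, g, cfg_all)), 0L)
  # 3 flank mismatches + placeholder = 4: found
  r4 <- read
  for (p in c(3, 8, 40))
    substr(r4, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(r4, p, p))[1]
  h <- alignUngapped(r4, g, cfg_all)
  expect_equal(h$start, 1001L)
  expect_equal(h$raw_ed, 4L)
})

test_that("pre-cap ungapped hits equal the brute-force oracle", {
  set.seed(33)
  for (rep in 1:4) {
    g0 <- generateGenome(nChroms = 2, lengths = c(2500, 1500),
                         seed = 100 + rep)
    g <- buildSeedIndex(g0, 10)
    reads <- character()
    for (i in 1:12) {
      chrom <- sample(seqNames(g), 1)
      s <- getChromSeq(g, chrom)
      st <- sample(nchar(s) - 52, 1)
      r <- substr(s, st, st + 52)
      substr(r, 27, 27) <- "?"
      nmut <- sample(0:5, 1)
      for (p in sample(setdiff(1:53, 27), nmut))
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      reads <- c(reads, r)
    }
    for (i in 1:4) {
      r <- random_dna(53)
      substr(r, 27, 27) <- "?"
      reads <- c(reads, r)
    }
    # short reads exercise the brute-force path
    for (i in 1:4) {
      r <- random_dna(24)
      substr(r, 12, 12) <- "?"
      reads <- c(reads, r)
    }
    for (r in reads) {
      expect_identical(hit_keys(alignUngapped(r, g, cfg_all)),
                       oracle_keys(oracle_all_placements(g, r, 4)))
    }
  }
})

test_that("hit order is deterministic and the cap is monotone", {
  g <- buildSeedIndex(referenceGenome(
    c(chr1 = strrep("A", 80), chr2 = strrep("A", 60))), 10)
  read <- paste0(strrep("A", 26), "?", strrep("A", 26))
  h <- alignUngapped(read, g, cfg_all)
  expect_true(all(diff(match(h$chrom, seqNames(g))) >= 0))
  within <- split(h$start, h$chrom)
  expect_true(all(vapply(within, function(x) !is.unsorted(x), TRUE)))
  h5 <- alignUngapped(read, g, pipelineConfig(maxHits = 5))
  h20 <- alignUngapped(read, g, pipelineConfig(maxHits = 20))
  expect_equal(nrow(h5), 5L)
  key <- function(x) paste(x$chrom, x$start, x$strand)
  expect_identical(key(h5), key(h20)[1:5])
})

test_that("gapped rescue recovers flank deletions with the right CIGAR", {
  set.seed(35)
  s <- random_dna(4000)
  lf <- substr(s, 2001, 2026)
  rf <- substr(s, 2028, 2053)
  lf_del <- paste0(substr(lf, 1, 9), substr(lf, 11, 26))  # drop base 10
  read <- paste0(lf_del, "?", rf)
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  expect_equal(nrow(alignUngapped(read, g, cfg_all)), 0L)
  h <- alignGapped(read, g, cfg_all)
  expect_true(nrow(h) >= 1L)
  best <- h[which.min(h$raw_ed), ]
  expect_equal(best$start, 2001L)
  expect_match(best$cigar, "1D")
  expect_equal(best$raw_ed, 2L)  # deletion + placeholder
  expect_equal(best$stage, "1-gapped")
  # cost agrees with an independent semi-global DP
  win <- substr(s, 2001 - 10, 2053 + 10)
  expect_equal(oracle_glocal_cost(read, win), 2L)
})

test_that("gapped rescue contains exact placements with all-M CIGAR", {
  set.seed(36)
  s <- random_dna(3000)
  read <- paste0(substr(s, 501, 526), "?", substr(s, 528, 553))
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  h <- alignGapped(read, g, cfg_all)
  expect_true(any(h$start == 501 & h$cigar == "53M" & h$raw_ed == 1))
})

test_that("gapped rescue rejects reads beyond the mismatch budget", {
  set.seed(37)
  s <- random_dna(3000)
  read <- paste0(substr(s, 1001, 1026), "?", substr(s, 1028, 1053))
  for (p in c(5, 10, 15, 35, 40, 45))
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, p, p))[1]
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  expect_equal(nrow(alignStage1(read, g, cfg_all)), 0L)
  # the oracle confirms the minimum cost exceeds the mismatch budget
  win <- substr(s, 991, 1063)
  expect_gt(oracle_glocal_cost(read, win), 4)
})

test_that("alignStage1 dispatches ungapped first, then gapped", {
  set.seed(38)
  s <- random_dna(3000)
  read <- paste0(substr(s, 701, 726), "?", substr(s, 728, 753))
  g <- buildSeedIndex(referenceGenome(c(chr1 = s)), 10)
  expect_equal(alignStage1(read, g, cfg_all)$stage, "1-ungapped")
  lf_del <- paste0(substr(s, 701, 712), substr(s, 714, 726))
  readD <- paste0(lf_del, "?", substr(s, 728, 753))
  expect_equal(unique(alignStage1(readD, g, cfg_all)$stage), "1-gapped")
  absent <- paste0(random_dna(26), "?", random_dna(26))
  expect_equal(nrow(alignStage1(absent, g, cfg_all)), 0L)
})
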