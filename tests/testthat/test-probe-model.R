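test_that("bracketed allele strings parse in both dialects", {
  p <- parseProbeString(
    "GCACTCTCACATGGATTAGGGAATTA[CG]ATGCAGACCTCCTGCACAACTGCCC")
  expect_equal(alleleList(p)[[1]], c("C", "G"))
  expect_equal(nchar(leftFlank(p)), 26L)
  expect_equal(nchar(rightFlank(p)), 25L)
  r <- probeReads(p)
  expect_equal(nchar(r$seq), 52L)
  expect_equal(r$offset, 26L)
  expect_equal(substr(r$seq, 27, 27), "?")

  q <- parseProbeString("a[c/g]t")
  expect_equal(leftFlank(q), "A")
  expect_equal(rightFlank(q), "T")
  expect_equal(alleleList(q)[[1]], c("C", "G"))
  expect_equal(probeReads(q)$seq, "A?T")

  tri <- parseProbeString("AC[A/C/T]GG")
  expect_equal(alleleList(tri)[[1]], c("A", "C", "T"))
})

test_that("malformed probe strings are rejected", {
  expect_error(parseProbeString("ACGT"), "exactly one")
  expect_error(parseProbeString("A[CG]T[AT]G"), "exactly one")
  expect_error(parseProbeString("A[CX]T"), "distinct A/C/G/T")
  expect_error(parseProbeString("A[C]T"), "2-4")
  expect_error(parseProbeString("A[CC]T"), "distinct")
})

test_that("parse and render are inverse on canonical input", {
  set.seed(42)
  for (i in 1:25) {
    lf <- random_dna(sample(5:30, 1))
    rf <- random_dna(sample(5:30, 1))
    al <- sample(c("A", "C", "G", "T"), sample(2:4, 1))
    s <- paste0(lf, "[", paste(al, collapse = ""), "]", rf)
    expect_identical(probeString(parseProbeString(s)), s)
  }
})

test_that("collapsed reads keep total length; empty-flank edge works", {
  set.seed(7)
  for (i in 1:10) {
    lf <- random_dna(sample(0:20, 1))
    rf <- random_dna(sample(5:20, 1))
    p <- SnpProbeSet("s", lf, rf, list(c("A", "G")))
    r <- probeReads(p)
    expect_equal(nchar(r$seq), nchar(lf) + 1L + nchar(rf))
    expect_equal(r$offset, nchar(lf))
  }
  p0 <- SnpProbeSet("edge", "", "ACG", list(c("A", "T")))
  r0 <- probeReads(p0)
  expect_equal(r0$offset, 0L)
  expect_equal(nchar(r0$seq), 4L)
  expect_error(SnpProbeSet("bad", "", "", list("A")), "both be empty")
})

test_that("reverse complement is an involution mapping the offset o -> L-1-o", {
  expect_identical(revComp("A?T"), "A?T")
  expect_identical(revComp("AA?T"), "A?TT")
  expect_identical(revComp("ACGT"), "ACGT")
  expect_error(revComp("AXGT"), "illegal character")
  set.seed(11)
  for (i in 1:20) {
    L <- sample(5:40, 1)
    off <- sample(0:(L - 1), 1)
    s <- random_dna(L)
    substr(s, off + 1, off + 1) <- "?"
    rc <- revComp(s)
    expect_identical(revComp(rc), s)
    expect_equal(as.integer(regexpr("?", rc, fixed = TRUE)) - 1L,
                 L - 1L - off)
    expect_identical(rc, oracle_revcomp(s))
  }
})

test_that("reverse-complemented probes swap flanks and complement alleles", {
  p <- parseProbeString("AACC[A/G]TTTT", snpId = "rs9")
  q <- revCompProbes(p)
  expect_equal(leftFlank(q), "AAAA")
  expect_equal(rightFlank(q), "GGTT")
  expect_setequal(alleleList(q)[[1]], c("T", "C"))
  expect_equal(snpId(q), "rs9")
})

test_that("Illumina-style manifests parse, with vendor-unmapped rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "[Heading]",
    "Descriptor File Name,chip",
    "[Assay]",
    "IlmnID,Name,SNP,Chr,MapInfo,TopGenomicSeq",
    "rs1-id,rs1,[A/G],2,1000,TT[A/G]CC",
    "rs2-id,rs2,[C/T],0,0,GGGG[C/T]AAAA",
    "rs3-id,rs3,[A/C],X,55,AC[A/C]GT"), path)
  p <- parseManifest(path)
  expect_equal(length(p), 3L)
  expect_equal(snpId(p), c("rs1", "rs2", "rs3"))
  expect_equal(declaredChrom(p), c("2", NA, "X"))
  expect_equal(declaredPos(p), c(1000L, NA, 55L))
  expect_equal(alleleList(p)[[1]], c("A", "G"))
  expect_equal(leftFlank(p)[1], "TT")
})

test_that("manifest errors name the missing column; bad rows are skipped", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Name,Chr,MapInfo,TopGenomicSeq",
               "rs1,2,1000,TT[A/G]CC"), path)
  expect_error(parseManifest(path), "SNP")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("Name,SNP,Chr,MapInfo,TopGenomicSeq",
               "rs1,[A/G],2,1000,TT[A/G]CC",
               "rs2,[C/T],3,2000,NOBRACKETS"), path2)
  expect_warning(p <- parseManifest(path2), "skipping")
  expect_equal(snpId(p), "rs1")
})

test_that("alternate sequence column is honoured", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Name,SNP,Chr,MapInfo,SourceSeq",
               "rs1,[A/G],2,1000,TT[A/G]CC"), path)
  p <- parseManifest(path, seqColumn = "SourceSeq")
  expect_equal(rightFlank(p), "CC")
})

test_that("probe FASTA + info files round-trip losslessly", {
  set.seed(3)
  n <- 50
  lf <- vapply(1:n, function(i) random_dna(sample(10:30, 1)), "")
  rf <- vapply(1:n, function(i) random_dna(sample(10:30, 1)), "")
  # include a flank N to confirm the placeholder stays distinguishable
  substr(lf[1], 3, 3) <- "N"
  al <- lapply(1:n, function(i) sample(c("A", "C", "G", "T"), 2))
  chrom <- ifelse(runif(n) < 0.2, NA, sample(c("chr1", "chr2"), n, TRUE))
  pos <- ifelse(is.na(chrom), NA_integer_, sample.int(100000, n))
  p <- SnpProbeSet(paste0("s", 1:n), lf, rf, al, chrom, pos)
  fa <- tempfile(fileext = ".fa")
  info <- tempfile(fileext = ".tsv")
  writeProbeInputs(p, fa, info)
  q <- readProbeInputs(fa, info)
  expect_identical(as.data.frame(q), as.data.frame(p))

  # empty set gives valid empty files
  e <- SnpProbeSet(character(), character(), character(), list())
  fa2 <- tempfile(fileext = ".fa")
  info2 <- tempfile(fileext = ".tsv")
  writeProbeInputs(e, fa2, info2)
  expect_true(file.exists(fa2) && file.exists(info2))
  expect_equal(length(readProbeInputs(fa2, info2)), 0L)
})

test_that("manifest writer round-trips through the manifest reader", {
  set.seed(5)
  p <- SnpProbeSet(paste0("m", 1:10),
                   vapply(1:10, function(i) random_dna(15), ""),
                   vapply(1:10, function(i) random_dna(15), ""),
                   lapply(1:10, function(i) sample(c("A", "C", "G", "T"), 2)),
                   c(rep("chr1", 8), NA, NA),
                   c(1:8 * 100L, NA, NA))
  path <- tempfile(fileext = ".csv")
  writeManifest(p, path)
  q <- parseManifest(path)
  expect_identical(as.data.frame(q), as.data.frame(p))
})
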