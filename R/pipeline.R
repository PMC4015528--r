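# Orchestration: Pass A (vendor-declared chromosome), Pass B (genome-wide
# re-run for unresolved and vendor-unmapped SNPs), result writing and the
# discrepancy audit against the vendor's coordinates.

.resolveOne <- function(probe, g, cfg, chroms, allowStage2, pass) {
  read <- probeReads(probe)
  out <- list(
    snp_id = snpId(probe), status = "unmapped",
    chrom = NA_character_, declared_chrom = declaredChrom(probe),
    original_pos = declaredPos(probe),
    mapped_pos = NA_integer_, strand = NA_character_,
    cigar = NA_character_, corrected_edit_distance = NA_integer_,
    mapq = NA_integer_, stage = NA_character_, pass = pass)
  reasons <- character()

  h1 <- alignStage1(read, g, cfg, chroms)
  sel <- list(status = "none")
  if (nrow(h1)) {
    c1 <- classifyHits(h1, probe, g)
    reasons <- c(reasons, c1$rejected$reason)
    sel <- selectBest(c1$accepted, "1", cfg)
  }
  if (sel$status != "unique" && allowStage2) {
    h2 <- alignStage2(read, g, cfg, chroms)
    if (nrow(h2)) {
      c2 <- classifyHits(h2, probe, g)
      reasons <- c(reasons, c2$rejected$reason)
      sel2 <- selectBest(c2$accepted, "2", cfg)
      if (sel2$status != "none") sel <- sel2
    }
  }

  if (sel$status == "unique") {
    hit <- sel$hit
    out$status <- "unique"
    out$chrom <- hit$chrom
    out$mapped_pos <- hit$snp_pos
    out$strand <- hit$strand
    out$cigar <- hit$cigar
    out$corrected_edit_distance <- hit$corrected_ed
    out$mapq <- sel$mapq
    out$stage <- hit$stage
  } else if (sel$status == "ambiguous") {
    out$status <- "ambiguous"
    out$mapq <- 0L
    out$stage <- sel$hit$stage
  } else if (any(reasons == "allele_mismatch") &&
             all(reasons %in% c("allele_mismatch", "in_insertion",
                                "ref_N"))) {
    # every candidate placement failed the allele check
    out$status <- "allele_filtered"
  }
  out
}

.rowsToFrame <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Run the three-stage mapping pipeline
#'
#' Pass A aligns every probe with a declared chromosome only against that
#' chromosome (stage 1, then stage 2 for stage-1 failures and
#' ambiguities, then resolution). Pass B re-runs probes still unresolved
#' after Pass A, plus vendor-unmapped probes and probes whose declared
#' chromosome is absent from the genome, against the whole genome; in
#' Pass B stage 2 runs only when \code{genomeWideStage2} (the "D" option)
#' is set. Exactly one result row per input probe, in input order.
#'
#' @param probes a \linkS4class{SnpProbeSet}.
#' @param g a \linkS4class{ReferenceGenome}; indexed with
#'   \code{seedLen} from \code{cfg} if not already.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param verbose emit per-stage counters.
#' @return A \linkS4class{SnpMapResult}.
#' @examples
#' g <- generateGenome(lengths = 4000, seed = 1)
#' fx <- plantProbes(g, n = 5, seed = 2)
#' res <- runPipeline(fx$probes, g)
#' mappedSnps(res)$status
#' @export
runPipeline <- function(probes, g, cfg = pipelineConfig(), verbose = FALSE) {
  if (!isIndexed(g)) g <- buildSeedIndex(g, cfg@seedLen)
  n <- length(probes)
  applyFun <- function(idx, fun) {
    if (cfg@workers > 1L && .Platform$OS.type == "unix")
      parallel::mclapply(idx, fun, mc.cores = cfg@workers)
    else
      lapply(idx, fun)
  }

  declared <- declaredChrom(probes)
  known <- !is.na(declared) & declared %in% seqNames(g)
  orphan <- !is.na(declared) & !known
  if (any(orphan))
    warning(sum(orphan), " probe(s) declare a chromosome absent from the ",
            "genome; routed to the genome-wide pass")

  results <- vector("list", n)
  passA <- which(known)
  resA <- applyFun(passA, function(i)
    .resolveOne(probes[i], g, cfg, declared[i], allowStage2 = TRUE,
                pass = "A"))
  for (j in seq_along(passA)) results[[passA[j]]] <- resA[[j]]

  unresolved <- vapply(results, function(r)
    is.null(r) || r$status != "unique", TRUE)
  passB <- which(unresolved)
  resB <- applyFun(passB, function(i)
    .resolveOne(probes[i], g, cfg, seqNames(g),
                allowStage2 = cfg@genomeWideStage2, pass = "B"))
  for (j in seq_along(passB)) results[[passB[j]]] <- resB[[j]]

  mapping <- .rowsToFrame(results)
  rownames(mapping) <- NULL
  if (verbose) {
    cnt <- table(factor(mapping$status,
                        levels = c("unique", "ambiguous", "unmapped",
                                   "allele_filtered")))
    message("mapped ", cnt[["unique"]], " / ", n, " uniquely; ",
            cnt[["ambiguous"]], " ambiguous, ", cnt[["unmapped"]],
            " unmapped, ", cnt[["allele_filtered"]], " allele-filtered (",
            sum(mapping$status == "unique" & mapping$stage == "2"),
            " rescued at stage 2)")
  }
  new("SnpMapResult", mapping = mapping, config = cfg)
}

#' Write pipeline results
#'
#' Tab-delimited, one row per SNP, header: snp_id, chrom, original_pos,
#' mapped_pos, strand, cigar, status, mapq, corrected_edit_distance,
#' stage. Absent values are rendered as ".".
#'
#' @param x a \linkS4class{SnpMapResult} (or its data.frame).
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writeResults <- function(x, path) {
  m <- if (is(x, "SnpMapResult")) x@mapping else x
  cols <- c("snp_id", "chrom", "original_pos", "mapped_pos", "strand",
            "cigar", "status", "mapq", "corrected_edit_distance", "stage")
  out <- m[cols]
  for (col in cols) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e)))
  invisible(out)
}

#' Audit mapped positions against the vendor's coordinates
#'
#' Classifies every SNP as identical (unique at the declared coordinate),
#' differently_mapped_same_chrom, differently_mapped_other_chrom,
#' newly_mapped (vendor-unmapped but uniquely resolved), unmapped
#' (including allele-filtered) or ambiguous, and lists the per-SNP
#' discrepancies.
#'
#' @param x a \linkS4class{SnpMapResult}.
#' @return list with \code{counts} (named integer vector) and
#'   \code{discrepancies} (data.frame of non-identical unique mappings).
#' @export
compareToDeclared <- function(x) {
  m <- if (is(x, "SnpMapResult")) x@mapping else x
  cat_ <- character(nrow(m))
  uniq <- m$status == "unique"
  hasPos <- !is.na(m$original_pos)
  declChrom <- if ("declared_chrom" %in% names(m)) m$declared_chrom else m$chrom
  cat_[m$status %in% c("unmapped", "allele_filtered")] <- "unmapped"
  cat_[m$status == "ambiguous"] <- "ambiguous"
  cat_[uniq & !hasPos] <- "newly_mapped"
  hasChrom <- !is.na(declChrom)
  same <- uniq & hasPos & hasChrom & declChrom == m$chrom
  cat_[same & m$original_pos == m$mapped_pos] <- "identical"
  cat_[same & m$original_pos != m$mapped_pos] <- "differently_mapped_same_chrom"
  cat_[uniq & hasPos & hasChrom & declChrom != m$chrom] <-
    "differently_mapped_other_chrom"
  lv <- c("identical", "differently_mapped_same_chrom",
          "differently_mapped_other_chrom", "newly_mapped", "unmapped",
          "ambiguous")
  counts <- table(factor(cat_, levels = lv))
  disc <- m[cat_ %in% lv[2:4], , drop = FALSE]
  disc$category <- cat_[cat_ %in% lv[2:4]]
  list(counts = stats::setNames(as.integer(counts), lv),
       discrepancies = disc)
}
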