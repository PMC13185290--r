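# two-transcript gene on a toy chromosome (1-based closed GTF coordinates)
two_tx_gtf <- function() {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrS\ttoy\tgene\t101\t400\t.\t+\t.\tgene_id \"G1\";",
    "chrS\ttoy\ttranscript\t101\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\texon\t101\t200\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\texon\t301\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\ttranscript\t101\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T2\";",
    "chrS\ttoy\texon\t101\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T2\";"),
    path)
  path
}

test_that("isoform index has one spliced model per transcript plus unspliced", {
  idx <- build_isoform_index(two_tx_gtf())
  expect_setequal(idx$spans$isoform_id,
                  c("T1_G1", "T2_G1", "G1_unspliced"))
  # 1-based closed 101-200, 301-400 -> 0-based half-open [100,200),[300,400)
  expect_equal(unname(idx$exons[["T1_G1"]]),
               unname(cbind(c(100L, 300L), c(200L, 400L))))
  expect_equal(unname(idx$exons[["G1_unspliced"]]),
               unname(cbind(100L, 400L)))
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_equal(length(build_isoform_index(empty)$exons), 0L)
})

test_that("block merging fuses gaps up to 10 bp and is idempotent", {
  expect_equal(unname(merge_read_blocks(cbind(c(100L, 205L), c(200L, 300L)))),
               unname(cbind(100L, 300L)))   # gap 5 fused
  b <- cbind(c(100L, 215L), c(200L, 300L))  # gap 15 kept
  expect_equal(unname(merge_read_blocks(b)), unname(b))
  g10 <- cbind(c(100L, 210L), c(200L, 300L))  # gap exactly 10 fused
  expect_equal(unname(merge_read_blocks(g10)), unname(cbind(100L, 300L)))
  one <- cbind(50L, 80L)
  expect_equal(unname(merge_read_blocks(one)), unname(one))
  m <- merge_read_blocks(cbind(c(100L, 205L, 400L), c(200L, 300L, 500L)))
  expect_equal(merge_read_blocks(m), m)  # idempotent
})

test_that("best-alignment filter keeps strict maxima only", {
  al <- function(q, s) list(qname = q, score = s)
  out <- best_alignment_filter(list(al("a", 100), al("a", 90), al("b", 50)))
  expect_equal(vapply(out, `[[`, numeric(1), "score"), c(100, 50))
  out2 <- best_alignment_filter(list(al("a", 100), al("a", 100)))
  expect_equal(length(out2), 0L)
  expect_equal(length(best_alignment_filter(list(al("x", 1)))), 1L)
})

test_that("isoform assignment applies the 95% and 10-bp rules", {
  idx <- build_isoform_index(two_tx_gtf())
  # read exactly matching T1's exons -> T1 (T2/unspliced overlap is
  # 200 of 300 trimmed bases = 67%, excluded by the 95% rule)
  expect_equal(assign_isoform(cbind(c(100L, 300L), c(200L, 400L)),
                              idx, "chrS"), "T1_G1")
  # intron-interior read: T2 and the unspliced model both cover it fully
  # and tie exactly -> discarded by the margin rule
  expect_equal(assign_isoform(cbind(210L, 290L), idx, "chrS"),
               NA_character_)
  expect_equal(assign_isoform(cbind(9000L, 9100L), idx, "chrS"),
               NA_character_)  # no candidate
  # runner-up within 10 bp -> no assignment: T1 vs a transcript whose
  # second exon starts 5 bp later
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrS\ttoy\ttranscript\t101\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\texon\t101\t200\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\texon\t301\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chrS\ttoy\ttranscript\t101\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T3\";",
    "chrS\ttoy\texon\t101\t200\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T3\";",
    "chrS\ttoy\texon\t306\t400\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T3\";",
    "chrS\ttoy\tgene\t9001\t9100\t.\t+\t.\tgene_id \"GX\";"), path)
  idx_rr <- build_isoform_index(path)
  # overlaps 200 (T1, exact) vs 195 (T3): difference 5 < 10 -> discarded
  expect_equal(assign_isoform(cbind(c(100L, 300L), c(200L, 400L)),
                              idx_rr, "chrS"), NA_character_)
})

test_that("pre-mRNA reads go to the unspliced isoform of single-isoform genes", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrS\ttoy\tgene\t101\t600\t.\t+\t.\tgene_id \"G2\";",
    "chrS\ttoy\ttranscript\t101\t600\t.\t+\t.\tgene_id \"G2\"; transcript_id \"T9\";",
    "chrS\ttoy\texon\t101\t200\t.\t+\t.\tgene_id \"G2\"; transcript_id \"T9\";",
    "chrS\ttoy\texon\t501\t600\t.\t+\t.\tgene_id \"G2\"; transcript_id \"T9\";"),
    path)
  idx <- build_isoform_index(path)
  # genomic fragment crossing the splice junction: spliced overlap is poor,
  # unspliced overlap is 100% of the read
  expect_equal(assign_isoform(cbind(150L, 550L), idx, "chrS"),
               "G2_unspliced")
  # read equal to the spliced exons: spliced wins (unspliced trimmed span
  # overlaps only 200/500 bases)
  expect_equal(assign_isoform(cbind(c(100L, 500L), c(200L, 600L)),
                              idx, "chrS"), "T9_G2")
})

test_that("the require_both switch controls the 95% exclusion", {
  # single-isoform gtf (exon-only, so no unspliced competitor)
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrS\ttoy\ttranscript\t101\t1000\t.\t+\t.\tgene_id \"G3\"; transcript_id \"TA\";",
    "chrS\ttoy\texon\t101\t1000\t.\t+\t.\tgene_id \"G3\"; transcript_id \"TA\";",
    "chrS\ttoy\tgene\t2001\t2100\t.\t+\t.\tgene_id \"GX\";"), path)
  idx <- build_isoform_index(path)
  # read with a 200-bp tail off the gene: overlap 500 bp = 100% of the
  # trimmed isoform but only 71% of the read
  rb <- cbind(500L, 1200L)
  expect_equal(assign_isoform(rb, idx, "chrS"), NA_character_)
  expect_equal(assign_isoform(rb, idx, "chrS", require_both = FALSE),
               "TA_G3")
})

test_that("assignment matches the brute-force oracle on random reads", {
  ann <- simulate_annotation(n_genes = 6, seed = 111, gene_len = 2000L,
                             transcripts_per_gene = 2L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(ann$gtf, gtf)
  idx <- build_isoform_index(gtf)
  set.seed(112)
  for (i in 1:60) {
    start <- sample(500:18000, 1)
    n_blocks <- sample(1:3, 1)
    bs <- start + cumsum(c(0, sample(50:400, n_blocks * 2 - 1)))
    blocks <- cbind(bs[seq(1, 2 * n_blocks - 1, by = 2)],
                    bs[seq(2, 2 * n_blocks, by = 2)])
    blocks <- merge_read_blocks(blocks)
    expect_identical(assign_isoform(blocks, idx, "chrS"),
                     oracle_assign_isoform(blocks, idx, "chrS"))
  }
})

test_that("genotype lookup votes follow phase, third alleles and deletions", {
  gt <- genotype_table("s", data.frame(
    chrom = "chrS", pos = c(104L, 110L), ref = c("A", "C"),
    alt = c("G", "T"), phase = c("REF_FIRST", "ALT_FIRST")))
  # query base G at a 0|1 SNP (A->G) -> the alt-carrying haplotype, HAP2
  s <- paste0(strrep("A", 4), "G", strrep("A", 15))
  aln <- list(chrom = "chrS", pos = 101L, cigar = "20M", seq = s)
  v <- genotype_overlap_alleles(aln, gt)
  expect_equal(v$vote[v$pos == 104L], "HAP2")
  # base A at the ALT_FIRST SNP (C->T): matches neither -> NEITHER
  expect_equal(v$vote[v$pos == 110L], "NEITHER")
  # ref base C at ALT_FIRST -> HAP2 (reference sits on haplotype 2)
  s2 <- paste0(strrep("A", 10), "C", strrep("A", 9))
  v2 <- genotype_overlap_alleles(list(chrom = "chrS", pos = 101L,
                                      cigar = "20M", seq = s2), gt)
  expect_equal(v2$vote[v2$pos == 110L], "HAP2")
  # SNP position inside a deletion -> NEITHER
  aln_del <- list(chrom = "chrS", pos = 101L, cigar = "3M5D12M",
                  seq = paste(rep("A", 15), collapse = ""))
  vd <- genotype_overlap_alleles(aln_del, gt)
  expect_equal(vd$vote[vd$pos == 104L], "NEITHER")
})

test_that("CIGAR statistics count matches, substitutions and indels", {
  s <- cigar_error_stats("50=1X49=")
  expect_equal(s$matched_bp, 99L)
  expect_equal(s$mismatches, 1L)
  expect_equal(s$mismatch_rate, 1 / 99)
  s2 <- cigar_error_stats("10=2I10=1D10=")
  expect_equal(s2$matched_bp, 30L)
  expect_equal(s2$insertions, 2L)
  expect_equal(s2$deletions, 1L)
  expect_error(cigar_error_stats("100M"), "cannot resolve")
  # MD resolution: 100M with two substitutions
  s3 <- cigar_error_stats("100M", md = "40A20T38")
  expect_equal(s3$matched_bp, 98L)
  expect_equal(s3$mismatches, 2L)
  # deletions in MD are not substitutions
  s4 <- cigar_error_stats("10M2D10M", md = "10^AC10")
  expect_equal(s4$mismatches, 0L)
  expect_equal(s4$matched_bp, 20L)
})

test_that("mapped length counts aligned bases only", {
  expect_equal(mapped_length("50=1X49="), 100L)
  expect_equal(mapped_length("10S90="), 90L)
  expect_equal(mapped_length("40=1000N40="), 80L)
  expect_equal(mapped_length("5H10M3I7M"), 17L)
})

test_that("exact-transcript reads are assigned; pre-mRNA reads go unspliced", {
  ann <- simulate_annotation(n_genes = 4, seed = 121, gene_len = 3000L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(ann$gtf, gtf)
  idx <- build_isoform_index(gtf)
  set.seed(122)
  n_spliced_ok <- 0; n_unspliced <- 0; n_tries <- 0
  for (g in unique(ann$exons$transcript_id)) {
    e <- ann$exons[ann$exons$transcript_id == g, ]
    blocks <- merge_read_blocks(cbind(e$start, e$end))
    iso <- assign_isoform(blocks, idx, "chrS")
    if (nrow(blocks) > 1) {
      n_tries <- n_tries + 1
      if (identical(iso, paste(g, e$gene_id[1], sep = "_")))
        n_spliced_ok <- n_spliced_ok + 1
    }
    # contiguous genomic fragment across the first splice junction
    if (nrow(blocks) > 1) {
      frag <- cbind(blocks[1, 2] - 50L, blocks[2, 1] + 50L)
      iso2 <- assign_isoform(frag, idx, "chrS")
      if (identical(iso2, paste(e$gene_id[1], "unspliced", sep = "_")))
        n_unspliced <- n_unspliced + 1
    }
  }
  expect_equal(n_spliced_ok, n_tries)
  expect_equal(n_unspliced, n_tries)
})

test_that("the long-read stream pipeline yields isoform-keyed allele counts", {
  ann <- simulate_annotation(n_genes = 3, seed = 131, gene_len = 3000L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(ann$gtf, gtf)
  idx <- build_isoform_index(gtf)
  gt <- simulate_genotypes(300, 1, het_rate = 0.9, seed = 132,
                           chrom_len = max(ann$genes$end))$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 3, umis_per_cell = 20,
                               read_len = 400L, seed = 133)
  stream <- assign_isoforms_stream(sim$alignments, idx, genotypes = gt)
  expect_gt(length(stream), 0)
  feats <- unlist(lapply(stream, `[[`, "features"))
  expect_true(all(feats %in% idx$spans$isoform_id))
  cnt <- count_feature_ase(stream, feature_source = "isoform")
  expect_true(all(cnt$feature %in% idx$spans$isoform_id))
  # contiguous gene-body fragments are dominated by unspliced assignments
  expect_gt(mean(grepl("unspliced", feats)), 0.5)
})
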