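test_that("read filters exclude multimappers and WASP failures", {
  expect_false(passes_read_filters(mk_read("r", "c", "u", "g", "HAP1", nh = 2L)))
  expect_false(passes_read_filters(mk_read("r", "c", "u", "g", "HAP1",
                                           wasp = "fail")))
  expect_true(passes_read_filters(mk_read("r", "c", "u", "g", "HAP1",
                                          wasp = "pass")))
  expect_true(passes_read_filters(mk_read("r", "c", "u", "g",
                                          wasp = "not_evaluated")))
})

test_that("read-level call uses a strict >95% majority", {
  expect_equal(read_allele_call("HAP1"), "HAP1")
  expect_equal(read_allele_call(c("HAP2", "HAP2")), "HAP2")
  # 20/21 = 0.952 > 0.95 -> accepted
  expect_equal(read_allele_call(rep(c("HAP1", "HAP2"), c(20, 1))), "HAP1")
  # 19/20 = 0.95 exactly -> rejected (strict inequality)
  expect_equal(read_allele_call(rep(c("HAP1", "HAP2"), c(19, 1))), "NONE")
  expect_equal(read_allele_call(character(0)), "NONE")
  expect_equal(read_allele_call(c("HAP1", "HAP2")), "NONE")
  expect_equal(read_allele_call("NEITHER"), "NONE")
})

test_that("UMI collapse resolves duplicates, conflicts and uninformative reads", {
  ledger <- data.frame(
    cell_barcode = "c1", feature = "g1",
    umi = c("u1", "u1", "u2", "u2", "u3", "u3"),
    call = c("HAP1", "HAP1",   # concordant duplicates -> hap1
             "HAP1", "HAP2",   # conflict -> ambiguous
             "HAP1", "NONE"),  # NONE does not dilute -> hap1
    stringsAsFactors = FALSE)
  out <- collapse_umis(ledger)
  expect_equal(out$hap1_umis, 2L)
  expect_equal(out$hap2_umis, 0L)
  expect_equal(out$ambiguous_umis, 1L)
  expect_equal(out$unphased_umis, 0L)
  only_none <- data.frame(cell_barcode = "c", feature = "g", umi = "u",
                          call = "NONE")
  expect_equal(collapse_umis(only_none)$unphased_umis, 1L)
  expect_equal(nrow(collapse_umis(ledger[0, ])), 0L)
})

# six-read hand fixture: 2 cells, 2 genes, one discordant UMI
hand_fixture <- function(feature_names = c("g1", "g2")) {
  f1 <- feature_names[1]; f2 <- feature_names[2]
  list(
    mk_read("r1", "c1", "u1", f1, "HAP1"),
    mk_read("r2", "c1", "u1", f1, "HAP1"),
    mk_read("r3", "c1", "u2", f1, "HAP1"),
    mk_read("r4", "c1", "u2", f1, "HAP2"),
    mk_read("r5", "c1", "u3", f2),
    mk_read("r6", "c2", "u1", f1, "HAP2"))
}

test_that("count_feature_ase reproduces the hand-traced table", {
  out <- count_feature_ase(hand_fixture())
  expect_equal(out[out$cell_barcode == "c1" & out$feature == "g1",
                   c("hap1_umis", "hap2_umis", "ambiguous_umis",
                     "unphased_umis")],
               data.frame(hap1_umis = 1L, hap2_umis = 0L,
                          ambiguous_umis = 1L, unphased_umis = 0L),
               ignore_attr = TRUE)
  expect_equal(out[out$cell_barcode == "c1" & out$feature == "g2",
                   "unphased_umis"], 1L)
  expect_equal(out[out$cell_barcode == "c2", "hap2_umis"], 1L)
  expect_equal(out, oracle_count_feature(hand_fixture()),
               ignore_attr = TRUE)
})

test_that("peak-keyed counting is identical to gene-keyed counting", {
  genes <- count_feature_ase(hand_fixture(c("g1", "g2")))
  peaks <- count_feature_ase(hand_fixture(c("pkA", "pkB")),
                             feature_source = "peak")
  expect_equal(genes[, -2], peaks[, -2], ignore_attr = TRUE)
  expect_equal(peaks$feature, c("pkA", "pkB", "pkA"))
})

test_that("featureless reads contribute no count rows", {
  s <- list(mk_read("r1", "c1", "u1", character(0), "HAP1"))
  expect_equal(nrow(count_feature_ase(s)), 0L)
})

test_that("counting matches the brute-force oracle on simulated reads", {
  ann <- simulate_annotation(n_genes = 5, seed = 61, gene_len = 3000L)
  gt <- simulate_genotypes(400, 1, het_rate = 0.8, seed = 62,
                           chrom_len = max(ann$genes$end))$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 4, umis_per_cell = 40,
                               true_ratios = stats::setNames(
                                 c(0.9, 0.7, 0.5, 0.3, 0.1),
                                 ann$genes$gene_id),
                               error_rate = 0.05, seed = 63)
  expect_equal(count_feature_ase(sim$stream),
               oracle_count_feature(sim$stream), ignore_attr = TRUE)
})

test_that("UMI categories conserve distinct UMIs and haplotype swap is exact", {
  ann <- simulate_annotation(n_genes = 3, seed = 71, gene_len = 3000L)
  gt <- simulate_genotypes(300, 1, het_rate = 0.8, seed = 72,
                           chrom_len = max(ann$genes$end))$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 3, umis_per_cell = 40,
                               error_rate = 0.1, seed = 73)
  out <- count_feature_ase(sim$stream)
  # conservation: the four categories partition distinct UMIs per key
  ledger <- build_umi_ledger(sim$stream)
  key <- paste(ledger$cell_barcode, ledger$feature)
  distinct <- tapply(ledger$umi, key, function(u) length(unique(u)))
  got <- out$hap1_umis + out$hap2_umis + out$ambiguous_umis +
    out$unphased_umis
  expect_equal(got, as.integer(distinct[paste(out$cell_barcode,
                                              out$feature)]),
               ignore_attr = TRUE)
  # swapping every HAP1<->HAP2 vote swaps hap columns only
  swapped <- lapply(sim$stream, function(o) {
    v <- o$snp_votes
    v$vote <- c(HAP1 = "HAP2", HAP2 = "HAP1", NEITHER = "NEITHER")[v$vote]
    o$snp_votes <- v
    o
  })
  out2 <- count_feature_ase(swapped)
  expect_equal(out2$hap1_umis, out$hap2_umis)
  expect_equal(out2$hap2_umis, out$hap1_umis)
  expect_equal(out2$ambiguous_umis, out$ambiguous_umis)
  expect_equal(out2$unphased_umis, out$unphased_umis)
})

test_that("SNP-level counting votes per SNP and translates phase to ref/alt", {
  ph <- c("REF_FIRST", "ALT_FIRST")
  r1 <- mk_read("r1", "c1", "u1", "g", c("HAP1", "HAP1"), phase = ph)
  out <- count_snp_level(list(r1))
  # REF_FIRST: HAP1 -> ref; ALT_FIRST: HAP1 -> alt
  expect_equal(out$ref_umis, c(1L, 0L))
  expect_equal(out$alt_umis, c(0L, 1L))
  expect_equal(nrow(out), 2L)  # one row per covered SNP
  # conflicting reads for the same UMI at one SNP -> ambiguous there
  r2 <- mk_read("r2", "c1", "u1", "g", c("HAP2", "HAP1"), phase = ph)
  out2 <- count_snp_level(list(r1, r2))
  expect_equal(out2$ambiguous_umis, c(1L, 0L))
  expect_equal(out2$alt_umis, c(0L, 1L))
  # NEITHER votes yield unphased UMIs at that SNP
  r3 <- mk_read("r3", "c2", "u9", "g", "NEITHER")
  expect_equal(count_snp_level(list(r3))$unphased_umis, 1L)
})

test_that("SNP-level ref fraction is centered at 50% under an unbiased simulation", {
  ann <- simulate_annotation(n_genes = 6, seed = 81, gene_len = 4000L)
  gt <- simulate_genotypes(600, 1, het_rate = 0.9, seed = 82,
                           chrom_len = max(ann$genes$end))$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 10, umis_per_cell = 150,
                               reads_per_umi = "constant", mean_reads = 1,
                               seed = 83)
  snp <- count_snp_level(sim$stream)
  ref <- sum(snp$ref_umis); tot <- sum(snp$ref_umis + snp$alt_umis)
  expect_gt(tot, 1000)
  bt <- stats::binom.test(ref, tot, p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("downsampling is seed-deterministic, query-grouped, and binomial", {
  ann <- simulate_annotation(n_genes = 2, seed = 91)
  gt <- simulate_genotypes(50, 1, seed = 92)$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 2, umis_per_cell = 20,
                               seed = 93)
  s <- sim$stream
  expect_identical(downsample_stream(s, 1, seed = 1), s)
  expect_error(downsample_stream(s, 0, seed = 1), "fraction")
  expect_error(downsample_stream(s, 1.2, seed = 1), "fraction")
  a <- downsample_stream(s, 0.5, seed = 7)
  b <- downsample_stream(s, 0.5, seed = 7)
  expect_identical(vapply(a, `[[`, character(1), "qname"),
                   vapply(b, `[[`, character(1), "qname"))
  # binomial 99% interval on kept count over many synthetic qnames
  many <- lapply(seq_len(10000), function(i)
    mk_read(sprintf("q%05d", i), "c", sprintf("u%05d", i), "g"))
  kept <- length(downsample_stream(many, 0.5, seed = 8))
  band <- stats::qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(kept, band[1]); expect_lte(kept, band[2])
})

test_that("SAM round trip preserves counts and tag semantics", {
  ann <- simulate_annotation(n_genes = 3, seed = 101, gene_len = 3000L)
  gt <- simulate_genotypes(300, 1, het_rate = 0.8, seed = 102,
                           chrom_len = max(ann$genes$end))$tables[[1]]
  sim <- simulate_tagged_reads(gt, ann, cells = 3, umis_per_cell = 30,
                               seed = 103)
  sam <- tempfile(fileext = ".sam")
  writeLines(sim$sam, sam)
  stream <- read_tagged_sam(sam, genotypes = gt)
  expect_equal(count_feature_ase(stream), count_feature_ase(sim$stream),
               ignore_attr = TRUE)
  expect_equal(count_snp_level(stream), count_snp_level(sim$stream),
               ignore_attr = TRUE)
})
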