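mk_genotypes <- function(phases) {
  # one SNP at chrS:999 per sample with the given phase; NA = not het
  out <- lapply(names(phases), function(s) {
    ph <- phases[[s]]
    snps <- if (is.na(ph)) {
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), phase = character(0))
    } else {
      data.frame(chrom = "chrS", pos = 999L, ref = "A", alt = "G",
                 phase = ph)
    }
    genotype_table(s, snps)
  })
  names(out) <- names(phases)
  out
}

test_that("orientation maps haplotypes to ref/alt through each sample's phase", {
  counts <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                       feature = "G1",
                       hap1_umis = c(10L, 10L, 10L, 10L),
                       hap2_umis = c(5L, 5L, 5L, 5L))
  gts <- mk_genotypes(list(s1 = "REF_FIRST", s2 = "ALT_FIRST",
                           s3 = NA, s4 = "UNPHASED"))
  o <- orient_gene_counts(counts, gts, list(chrom = "chrS", pos = 999L))
  expect_equal(o$sample, c("s1", "s2"))      # non-het and unphased dropped
  expect_equal(o$ref_umis, c(10L, 5L))       # 1|0 swaps the columns
  expect_equal(o$alt_umis, c(5L, 10L))
  o2 <- orient_gene_counts(counts, gts, list(chrom = "chrS", pos = 999L),
                           include_unphased = TRUE)
  expect_equal(o2$sample, c("s1", "s2", "s4"))
  expect_warning(
    orient_gene_counts(counts, mk_genotypes(list(s1 = NA, s2 = NA, s3 = NA,
                                                 s4 = NA)),
                       list(chrom = "chrS", pos = 999L)),
    "no sample")
})

test_that("flipping every phase at the query SNP swaps ref and alt exactly", {
  set.seed(141)
  counts <- data.frame(sample = sprintf("s%d", 1:8), feature = "G1",
                       hap1_umis = rpois(8, 20), hap2_umis = rpois(8, 20))
  ph <- sample(c("REF_FIRST", "ALT_FIRST"), 8, TRUE)
  names(ph) <- counts$sample
  flipped <- stats::setNames(
    ifelse(ph == "REF_FIRST", "ALT_FIRST", "REF_FIRST"), names(ph))
  a <- orient_gene_counts(counts, mk_genotypes(as.list(ph)),
                          list(chrom = "chrS", pos = 999L))
  b <- orient_gene_counts(counts, mk_genotypes(as.list(flipped)),
                          list(chrom = "chrS", pos = 999L))
  expect_equal(a$ref_umis, b$alt_umis)
  expect_equal(a$alt_umis, b$ref_umis)
})

test_that("expression filters use strict thresholds on samples and UMIs", {
  mk <- function(n_samples, umis)
    data.frame(snp = "s1", feature = "G1",
               sample = sprintf("i%02d", seq_len(n_samples)),
               ref_umis = umis, alt_umis = 0L)
  # 11 UMIs in 6 samples: 11 > 10 in 6 > 5 samples -> retained
  expect_equal(nrow(apply_expression_filters(mk(6, 11L))), 6L)
  # 11 UMIs in exactly 5 samples -> dropped
  expect_equal(nrow(apply_expression_filters(mk(5, 11L))), 0L)
  # 10 UMIs (not > 10) in 20 samples -> dropped
  expect_equal(nrow(apply_expression_filters(mk(20, 10L))), 0L)
  expect_equal(attr(apply_expression_filters(mk(5, 11L)), "dropped"),
               "s1\rG1")
})

test_that("relaxing either filter threshold never drops a retained feature", {
  set.seed(151)
  o <- data.frame(snp = rep(sprintf("s%02d", 1:20), each = 8),
                  feature = "G", sample = rep(sprintf("i%d", 1:8), 20),
                  ref_umis = rpois(160, 8), alt_umis = rpois(160, 8))
  strict <- unique(apply_expression_filters(o, filter_config(10, 5))$snp)
  for (cfg in list(filter_config(5, 5), filter_config(10, 3),
                   filter_config(0, 0))) {
    relaxed <- unique(apply_expression_filters(o, cfg)$snp)
    expect_true(all(strict %in% relaxed))
  }
})

test_that("pseudobulk sums within groups and conserves totals", {
  counts <- data.frame(
    cell_barcode = c("c1", "c2", "c3", "c4"),
    feature = "G1",
    hap1_umis = c(3L, 4L, 7L, 1L), hap2_umis = c(1L, 0L, 2L, 5L),
    ambiguous_umis = 0L, unphased_umis = c(0L, 2L, 0L, 0L))
  meta <- data.frame(cell_barcode = c("c1", "c2", "c3", "c4"),
                     sample = c("s1", "s1", "s1", "s2"),
                     cell_type = c("neuron", "neuron", "glia", "neuron"))
  pb <- pseudobulk(counts, meta)
  expect_equal(nrow(pb), 3L)  # (s1,neuron) (s1,glia) (s2,neuron)
  expect_equal(pb$hap1_umis[pb$sample == "s1" & pb$cell_type == "neuron"], 7L)
  expect_equal(sum(pb$hap1_umis), sum(counts$hap1_umis))
  expect_equal(sum(pb$unphased_umis), sum(counts$unphased_umis))
  expect_error(pseudobulk(counts, meta[-1, ]), "c1")
  expect_equal(nrow(pseudobulk(counts[0, ], meta)), 0L)
})

test_that("individual downsampling is deterministic and unbiased", {
  samples <- sprintf("i%02d", 1:94)
  expect_setequal(downsample_individuals(samples, 94, seed = 1), samples)
  expect_identical(downsample_individuals(samples, 10, seed = 5),
                   downsample_individuals(samples, 10, seed = 5))
  expect_error(downsample_individuals(samples, 95, seed = 1), "95")
  path <- tempfile()
  sel <- downsample_individuals(samples, 10, seed = 6, save_to = path)
  expect_identical(readLines(path), sel)
  # inclusion frequency of each sample across 1000 repetitions stays inside
  # the 99% binomial band of 10/94
  hits <- integer(94); names(hits) <- samples
  for (r in 1:1000) {
    s <- downsample_individuals(samples, 10, seed = 1000 + r)
    hits[s] <- hits[s] + 1L
  }
  band <- stats::qbinom(c(0.005, 0.995), 1000, 10 / 94)
  expect_true(all(hits >= band[1] & hits <= band[2]))
})

test_that("pseudobulk then orientation feeds the test layer end to end", {
  ann <- simulate_annotation(n_genes = 2, seed = 161, gene_len = 4000L)
  chrom_len <- max(ann$genes$end)
  cohort <- simulate_genotypes(400, 6, het_rate = 0.9, seed = 170,
                               chrom_len = chrom_len)
  gts <- list()
  oriented_rows <- list()
  for (i in 1:6) {
    gt <- cohort$tables[[i]]
    gt$sample_id <- sprintf("ind%d", i)
    gts[[gt$sample_id]] <- gt
    sim <- simulate_tagged_reads(gt, ann, cells = 4, umis_per_cell = 60,
                                 true_ratios = c(G01 = 0.85, G02 = 0.5),
                                 seed = 180 + i)
    cnt <- count_feature_ase(sim$stream)
    meta <- data.frame(cell_barcode = unique(cnt$cell_barcode),
                       sample = gt$sample_id, cell_type = "neuron")
    pb <- pseudobulk(cnt, meta)
    oriented_rows[[i]] <- pb[pb$feature == "G01", , drop = FALSE]
  }
  counts <- do.call(rbind, oriented_rows)
  # query SNP: first G01-body SNP het in every individual
  g1 <- ann$genes[ann$genes$gene_id == "G01", ]
  cand <- Reduce(intersect, lapply(gts, function(g)
    het_snps_overlapping(g, "chrS", cbind(g1$start, g1$end))$pos))
  cand <- cand[vapply(cand, function(p) all(vapply(gts, function(g)
    g$snps$phase[g$snps$pos == p] != "UNPHASED", logical(1))), logical(1))]
  expect_gt(length(cand), 0)
  o <- orient_gene_counts(counts, gts,
                          list(chrom = "chrS", pos = cand[1]))
  expect_equal(nrow(o), 6L)
  expect_gt(sum(o$ref_umis + o$alt_umis), 200)
  # truth: P(haplotype 1) = 0.85, so the oriented ref fraction is 0.85 for
  # samples whose reference allele sits on haplotype 1 and 0.15 otherwise
  exp_p <- vapply(o$sample, function(s) {
    g <- gts[[s]]
    ph <- g$snps$phase[g$snps$pos == cand[1]]
    if (ph == "REF_FIRST") 0.85 else 0.15
  }, numeric(1))
  obs <- o$ref_umis / (o$ref_umis + o$alt_umis)
  expect_lt(mean(abs(obs - exp_p)), 0.12)
})
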