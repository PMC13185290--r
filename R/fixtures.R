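# Synthetic-data generators: toy genotypes, annotations, tagged reads and
# beta-binomial counts with known truth, so that every pipeline stage is
# testable without external data. All generators are seed-deterministic and
# emit valid standard-format text (VCF/GTF/SAM) parseable by the package's
# own readers.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate phased genotypes for a cohort
#'
#' Draws SNP positions on a toy chromosome; per sample, each SNP is
#' heterozygous with probability `het_rate` (phase uniform over `0|1` and
#' `1|0`) and otherwise homozygous. Returns per-sample genotype tables and
#' multi-sample VCF text that round-trips through [load_genotypes()].
#'
#' @param n_snps Number of SNP sites.
#' @param n_samples Number of individuals.
#' @param het_rate Per-sample heterozygosity probability.
#' @param seed Integer seed.
#' @param chrom,chrom_len Toy chromosome name and length.
#' @param phase_unphased Emit unphased (`0/1`) het genotypes instead of
#'   phased ones.
#' @return A list: `tables` (named list of [genotype_table()]), `sites`
#'   (data.frame of all SNP sites), `vcf` (character lines). Use
#'   `writeLines(x$vcf, path)` to materialize the VCF.
#' @export
simulate_genotypes <- function(n_snps, n_samples, het_rate = 0.5, seed = 1L,
                               chrom = "chrS", chrom_len = 1e6L,
                               phase_unphased = FALSE) {
  stopifnot_prob(het_rate, "het_rate")
  with_seed(seed, {
    pos <- sort(sample(seq_len(chrom_len - 2L), n_snps))  # 0-based, < len
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    gt <- matrix("", n_snps, n_samples)
    for (j in seq_len(n_samples)) {
      is_het <- stats::runif(n_snps) < het_rate
      phase_flip <- stats::runif(n_snps) < 0.5
      hom_alt <- stats::runif(n_snps) < 0.5
      gt[, j] <- ifelse(is_het,
                        if (phase_unphased) "0/1" else
                          ifelse(phase_flip, "1|0", "0|1"),
                        ifelse(hom_alt, "1|1", "0|0"))
    }
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
    tables <- lapply(seq_len(n_samples), function(j) {
      het <- gt[, j] %in% c("0|1", "1|0", "0/1")
      genotype_table(sample_ids[j], data.frame(
        chrom = chrom, pos = pos[het], ref = ref[het], alt = alt[het],
        phase = c(`0|1` = "REF_FIRST", `1|0` = "ALT_FIRST",
                  `0/1` = "UNPHASED")[gt[het, j]],
        stringsAsFactors = FALSE))
    })
    names(tables) <- sample_ids
    vcf <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom, chrom_len),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"),
             vapply(seq_len(n_snps), function(i)
               paste(c(chrom, pos[i] + 1L, ".", ref[i], alt[i], ".", ".",
                       ".", "GT", gt[i, ]), collapse = "\t"), character(1)))
    list(tables = tables, sites = sites, vcf = vcf)
  })
}

#' Simulate a toy gene annotation
#'
#' Lays out non-overlapping genes (alternating strands) along a toy
#' chromosome, each with 1-3 transcripts of 2-4 exons; GTF text (1-based
#' closed coordinates) is emitted alongside the parsed structures. With
#' `overlapping = TRUE` consecutive gene pairs overlap, for testing
#' multi-feature reads.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param chrom Toy chromosome name.
#' @param gene_len Gene body length.
#' @param gap Gap between consecutive genes.
#' @param transcripts_per_gene Transcript count per gene (recycled).
#' @param overlapping Make consecutive genes overlap.
#' @return A list: `genes` (data.frame with `gene_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`), `exons` (data.frame with
#'   `transcript_id`), `gtf` (character lines).
#' @export
simulate_annotation <- function(n_genes = 8L, seed = 1L, chrom = "chrS",
                                gene_len = 5000L, gap = 2000L,
                                transcripts_per_gene = 1L,
                                overlapping = FALSE) {
  with_seed(seed, {
    tpg <- rep_len(transcripts_per_gene, n_genes)
    step <- if (overlapping) gene_len %/% 2L + gap else gene_len + gap
    gstart <- 1000L + (seq_len(n_genes) - 1L) * step  # 0-based
    genes <- data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                        chrom = chrom, start = gstart,
                        end = gstart + gene_len,
                        strand = rep_len(c("+", "-"), n_genes),
                        stringsAsFactors = FALSE)
    ex <- list()
    for (i in seq_len(n_genes)) {
      for (t in seq_len(tpg[i])) {
        tid <- sprintf("%s.T%d", genes$gene_id[i], t)
        n_ex <- sample(2:4, 1L)
        # partition the gene body into exons separated by introns
        cuts <- sort(sample(seq(200L, gene_len - 200L, by = 50L),
                            2L * n_ex - 2L))
        bounds <- c(0L, cuts, gene_len)
        for (e in seq_len(n_ex)) {
          ex[[length(ex) + 1L]] <- data.frame(
            gene_id = genes$gene_id[i], transcript_id = tid, chrom = chrom,
            start = genes$start[i] + bounds[2L * e - 1L],
            end = genes$start[i] + bounds[2L * e],
            strand = genes$strand[i], stringsAsFactors = FALSE)
        }
      }
    }
    exons <- do.call(rbind, ex)
    attr_of <- function(gid, tid = NULL)
      if (is.null(tid))
        sprintf("gene_id \"%s\";", gid)
      else
        sprintf("gene_id \"%s\"; transcript_id \"%s\";", gid, tid)
    gtf <- c(
      vapply(seq_len(n_genes), function(i)
        paste(chrom, "toy", "gene", genes$start[i] + 1L, genes$end[i], ".",
              genes$strand[i], ".", attr_of(genes$gene_id[i]), sep = "\t"),
        character(1)),
      unlist(lapply(unique(exons$transcript_id), function(tid) {
        e <- exons[exons$transcript_id == tid, , drop = FALSE]
        c(paste(chrom, "toy", "transcript", min(e$start) + 1L, max(e$end),
                ".", e$strand[1L], ".", attr_of(e$gene_id[1L], tid),
                sep = "\t"),
          vapply(seq_len(nrow(e)), function(j)
            paste(chrom, "toy", "exon", e$start[j] + 1L, e$end[j], ".",
                  e$strand[j], ".", attr_of(e$gene_id[1L], tid), sep = "\t"),
            character(1)))
      })))
    list(genes = genes, exons = exons, gtf = gtf)
  })
}

# alleles carried by haplotype `hap` (1 or 2) at SNP rows (vectorized);
# UNPHASED sites are stored ref-first
hap_alleles <- function(snps, hap) {
  ref_on_hap1 <- snps$phase != "ALT_FIRST"
  ifelse((hap == 1L) == ref_on_hap1, snps$ref, snps$alt)
}

bases_to_votes <- function(b, snps) {
  alt_first <- snps$phase == "ALT_FIRST"
  ifelse(b == snps$ref, ifelse(alt_first, "HAP2", "HAP1"),
         ifelse(b == snps$alt, ifelse(alt_first, "HAP1", "HAP2"),
                "NEITHER"))
}

#' Simulate tagged reads with known allelic truth
#'
#' Generates barcoded, UMI-tagged reads for one individual: each UMI picks a
#' gene, draws its haplotype of origin from the gene's true reference
#' fraction, and emits one or more reads placed uniformly in the gene body.
#' Reads covering heterozygous SNPs carry the haplotype's allele, flipped to
#' a random other base with probability `error_rate` per covered SNP. Both
#' short-read style records (pre-annotated votes, SAM text with
#' `CB`/`UB`/`GN`/`NH`/`vW`/`vA`/`vG` tags) and long-read style records
#' (query sequences for direct genotype lookup) are produced.
#'
#' @param genotypes A [genotype_table()] for the simulated individual.
#' @param annotation A [simulate_annotation()] result.
#' @param cells Number of cells.
#' @param umis_per_cell UMIs per cell.
#' @param reads_per_umi `"geometric"` (mean `mean_reads`) or `"constant"`
#'   (exactly `mean_reads`, rounded).
#' @param mean_reads Mean reads per UMI, default 1.5.
#' @param true_ratios Named per-gene probability that a UMI originates from
#'   haplotype 1 (default 0.5 everywhere).
#' @param error_rate Per-covered-SNP substitution probability.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return A list: `stream` (list of [read_obs()]), `truth` (per-UMI
#'   data.frame with the originating haplotype), `sam` (character lines),
#'   `alignments` (long-read records for [genotype_overlap_alleles()] /
#'   [assign_isoforms_stream()]).
#' @export
simulate_tagged_reads <- function(genotypes, annotation, cells = 10L,
                                  umis_per_cell = 50L,
                                  reads_per_umi = c("geometric", "constant"),
                                  mean_reads = 1.5, true_ratios = NULL,
                                  error_rate = 0, read_len = 90L,
                                  seed = 1L) {
  reads_per_umi <- match.arg(reads_per_umi)
  stopifnot_prob(error_rate, "error_rate")
  genes <- annotation$genes
  if (is.null(true_ratios))
    true_ratios <- stats::setNames(rep(0.5, nrow(genes)), genes$gene_id)
  stopifnot(all(true_ratios >= 0 & true_ratios <= 1))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    stream <- list(); sam_body <- list(); alignments <- list()
    truth <- list()
    read_i <- 0L
    for (ci in seq_len(cells)) {
      cb <- sprintf("CB%03d", ci)
      for (ui in seq_len(umis_per_cell)) {
        umi <- sprintf("U%05d", ui)
        gi <- sample(nrow(genes), 1L)
        gene <- genes[gi, ]
        ratio <- true_ratios[[gene$gene_id]]
        hap <- if (stats::runif(1) < ratio) 1L else 2L
        n_reads <- if (reads_per_umi == "constant") max(1L, round(mean_reads))
        else 1L + stats::rgeom(1L, prob = 1 / mean_reads)
        truth[[length(truth) + 1L]] <- data.frame(
          cell_barcode = cb, umi = umi, gene = gene$gene_id, hap = hap,
          n_reads = n_reads, stringsAsFactors = FALSE)
        for (ri in seq_len(n_reads)) {
          read_i <- read_i + 1L
          qname <- sprintf("r%07d", read_i)
          start <- gene$start +
            sample.int(max(gene$end - gene$start - read_len, 1L), 1L) - 1L
          blocks <- as_blocks(cbind(start, start + read_len))
          # which genes does the read overlap (features tag)
          feat <- genes$gene_id[genes$start < start + read_len &
                                  genes$end > start]
          snps <- het_snps_overlapping(genotypes, gene$chrom, blocks)
          seq_bases <- sample(bases, read_len, replace = TRUE)
          votes <- empty_votes()
          if (nrow(snps)) {
            b <- hap_alleles(snps, hap)
            if (error_rate > 0) {
              flip <- stats::runif(length(b)) < error_rate
              if (any(flip))
                b[flip] <- vapply(b[flip], function(x)
                  sample(setdiff(bases, x), 1L), character(1))
            }
            seq_bases[snps$pos - start + 1L] <- b
            vote <- bases_to_votes(b, snps)
            votes <- data.frame(snp = snp_key(snps$chrom, snps$pos),
                                pos = snps$pos, vote = vote,
                                phase = snps$phase, stringsAsFactors = FALSE)
          }
          wasp <- if (nrow(votes)) "pass" else "not_evaluated"
          stream[[read_i]] <- read_obs(
            qname = qname, chrom = gene$chrom, cell_barcode = cb, umi = umi,
            features = feat, n_alignments = 1L, wasp_pass = wasp,
            blocks = blocks, snp_votes = votes, strand = gene$strand)
          seq_str <- paste(seq_bases, collapse = "")
          tags <- c(sprintf("CB:Z:%s", cb), sprintf("UB:Z:%s", umi),
                    if (length(feat))
                      sprintf("GN:Z:%s", paste(feat, collapse = ";")),
                    "NH:i:1", sprintf("AS:i:%d", read_len),
                    if (nrow(votes)) c(
                      "vW:i:1",
                      sprintf("vA:B:c,%s", paste(
                        c(HAP1 = 1L, HAP2 = 2L, NEITHER = 3L)[votes$vote],
                        collapse = ",")),
                      sprintf("vG:B:i,%s", paste(votes$pos, collapse = ","))))
          sam_body[[read_i]] <- paste(
            c(qname, if (gene$strand == "-") 16L else 0L, gene$chrom,
              start + 1L, 255L, sprintf("%dM", read_len), "*", 0L, 0L,
              seq_str, paste(rep("I", read_len), collapse = ""), tags),
            collapse = "\t")
          alignments[[read_i]] <- list(
            qname = qname, chrom = gene$chrom, pos = start + 1L,
            cigar = sprintf("%dM", read_len), seq = seq_str,
            strand = gene$strand, score = read_len, cell_barcode = cb,
            umi = umi)
        }
      }
    }
    chrom_len <- max(genes$end) + 10000L
    sam <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", genes$chrom[1L], chrom_len),
             unlist(sam_body))
    list(stream = stream, truth = do.call(rbind, truth), sam = sam,
         alignments = alignments)
  })
}

#' Simulate beta-binomial allelic counts with known truth
#'
#' Implements the package's generative model: per feature j and sample s,
#' `k ~ BetaBinomial(n, logistic(logit(mu_j) + b_s + delta * condition_s),
#' rho)` with `b_s ~ Normal(0, sigma_b^2)`. Depths are Poisson with mean
#' `depth` (floored at 1). With `cells_per_sample` set, cell-level rows are
#' generated (depth divided across cells) for mixed-model input.
#'
#' @param n_samples,n_features Cohort dimensions.
#' @param mu Per-feature mean reference fraction (scalar or length
#'   `n_features`).
#' @param rho Intra-class correlation in `[0, 1)`.
#' @param depth Mean phased-UMI depth per (sample, feature).
#' @param sigma_b Random-intercept standard deviation across samples.
#' @param condition_effect Logit shift added for condition `"B"` (the second
#'   half of the samples).
#' @param cells_per_sample If set, emit cell-level rows.
#' @param seed Integer seed.
#' @return An oriented-counts data.frame (`feature`, `snp`, `sample`,
#'   `condition`, `ref_umis`, `alt_umis`; plus `cell_barcode` at cell
#'   level), with attribute `truth` (per-feature `mu`, per-sample `b`).
#' @export
simulate_betabinom_counts <- function(n_samples = 30L, n_features = 200L,
                                      mu = 0.5, rho = 0.1, depth = 100,
                                      sigma_b = 0, condition_effect = 0,
                                      cells_per_sample = NULL, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, sigma_b >= 0, depth > 0)
  mu <- rep_len(mu, n_features)
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    condition <- ifelse(seq_len(n_samples) <= n_samples / 2, "A", "B")
    b_s <- stats::rnorm(n_samples, 0, sigma_b)
    rows <- list()
    for (j in seq_len(n_features)) {
      eta <- stats::qlogis(pmin(pmax(mu[j], 1e-6), 1 - 1e-6)) + b_s +
        condition_effect * (condition == "B")
      if (is.null(cells_per_sample)) {
        n <- pmax(stats::rpois(n_samples, depth), 1L)
        k <- rbetabinom(n_samples, n, stats::plogis(eta), rho)
        rows[[j]] <- data.frame(
          feature = sprintf("f%03d", j), snp = sprintf("s%03d", j),
          sample = samples, condition = condition,
          ref_umis = k, alt_umis = n - k, stringsAsFactors = FALSE)
      } else {
        cell_rows <- lapply(seq_len(n_samples), function(s) {
          n <- pmax(stats::rpois(cells_per_sample,
                                 depth / cells_per_sample), 1L)
          k <- rbetabinom(cells_per_sample, n, stats::plogis(eta[s]), rho)
          data.frame(
            feature = sprintf("f%03d", j), snp = sprintf("s%03d", j),
            sample = samples[s], condition = condition[s],
            cell_barcode = sprintf("%s_CB%03d", samples[s],
                                   seq_len(cells_per_sample)),
            ref_umis = k, alt_umis = n - k, stringsAsFactors = FALSE)
        })
        rows[[j]] <- do.call(rbind, cell_rows)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(mu = mu, b = b_s, rho = rho,
                               sigma_b = sigma_b,
                               condition_effect = condition_effect)
    out
  })
}
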