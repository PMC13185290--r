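#' Build a region annotation index from a GTF
#'
#' Extracts gene, exon and UTR intervals for classifying reads into genomic
#' region categories. Antisense intervals are the gene bodies with strand
#' flipped.
#'
#' @param gtf Path to a GTF file, or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @return A list of `GRanges` (`genes`, `exons`, `utr3`, `utr5`,
#'   `antisense`) of class `region_annotation`.
#' @export
build_region_annotation <- function(gtf) {
  gr <- import_gtf(gtf)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) {
    # derive gene bodies from transcript/exon extent
    tx <- gr[type %in% c("transcript", "exon")]
    genes <- unlist(range(S4Vectors::split(tx, tx$gene_id)))
    genes$gene_id <- names(genes)
  }
  anti <- genes
  BiocGenerics::strand(anti) <- ifelse(
    as.character(BiocGenerics::strand(genes)) == "+", "-", "+")
  structure(list(
    genes = genes,
    exons = gr[type == "exon"],
    utr3 = gr[type %in% c("three_prime_utr", "3UTR", "three_prime_UTR")],
    utr5 = gr[type %in% c("five_prime_utr", "5UTR", "five_prime_UTR")],
    antisense = anti), class = "region_annotation")
}

obs_granges <- function(obs) {
  b <- obs$blocks
  if (nrow(b) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(obs$chrom, blocks_to_iranges(b),
                         strand = obs$strand)
}

#' Classify a read into a genomic region category
#'
#' Precedence: exonic (with 3'/5' UTR as subclasses) beats intronic (inside
#' the gene body but touching no exon), which beats antisense (overlapping
#' only an opposite-strand gene), which beats intergenic. Overlap is
#' strand-aware for the sense categories.
#'
#' @param obs A [read_obs()].
#' @param annotation A [build_region_annotation()] index.
#' @return One of `"exonic"`, `"utr3"`, `"utr5"`, `"intronic"`,
#'   `"antisense"`, `"intergenic"`.
#' @export
annotate_region <- function(obs, annotation) {
  gr <- obs_granges(obs)
  if (length(gr) == 0L) return("intergenic")
  hits <- function(subject, ignore_strand = FALSE)
    length(GenomicRanges::findOverlaps(gr, subject,
                                       ignore.strand = ignore_strand)) > 0L
  if (hits(annotation$exons)) {
    if (length(annotation$utr3) && hits(annotation$utr3)) return("utr3")
    if (length(annotation$utr5) && hits(annotation$utr5)) return("utr5")
    return("exonic")
  }
  if (hits(annotation$genes)) return("intronic")
  if (hits(annotation$antisense)) return("antisense")
  "intergenic"
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell present in the stream: read and UMI totals, the
#' number and percentage of phased UMIs (UMIs assignable to a haplotype), the
#' fraction of uniquely mapped reads in each genomic region category, the
#' fraction of reads that are spliced (more than one aligned block) or
#' multimapping, and — per region — the fraction of reads overlapping a
#' heterozygous SNP. Also returns the reads-per-UMI distribution, split by
#' whether the UMI's feature is in a supplied target set (e.g. hybrid
#' selection baits).
#'
#' @param stream List of [read_obs()] (the same stream used for counting).
#' @param counts Counts from [count_feature_ase()] for the same stream.
#' @param annotation Optional [build_region_annotation()]; without it region
#'   fractions are `NA`.
#' @param target_features Optional character vector of on-target features.
#' @return A data.frame with one row per cell; attribute `reads_per_umi` is a
#'   data.frame (`cell_barcode`, `feature`, `umi`, `n_reads`, `on_target`).
#' @export
compute_cell_qc <- function(stream, counts, annotation = NULL,
                            target_features = NULL) {
  if (length(stream) == 0L)
    return(data.frame(cell_barcode = character(0)))
  cb <- vapply(stream, `[[`, character(1), "cell_barcode")
  nh <- vapply(stream, `[[`, integer(1), "n_alignments")
  spliced <- vapply(stream, function(o) nrow(o$blocks) > 1L, logical(1))
  het_overlap <- vapply(stream, function(o) nrow(o$snp_votes) > 0L, logical(1))
  region <- if (is.null(annotation)) rep(NA_character_, length(stream)) else
    vapply(stream, annotate_region, character(1), annotation = annotation)

  uniq <- nh == 1L
  cells <- sort(unique(cb))
  per_cell <- lapply(cells, function(cell) {
    i <- cb == cell
    iu <- i & uniq
    n_reads <- sum(i)
    reg <- region[iu]
    frac <- function(lab) if (sum(iu) == 0L) NA_real_ else mean(reg %in% lab)
    het_frac <- function(lab) {
      j <- iu & region %in% lab
      if (sum(j) == 0L) NA_real_ else mean(het_overlap[j])
    }
    cnt <- counts[counts$cell_barcode == cell, , drop = FALSE]
    n_umis <- sum(cnt$hap1_umis + cnt$hap2_umis + cnt$ambiguous_umis +
                    cnt$unphased_umis)
    n_phased <- sum(cnt$hap1_umis + cnt$hap2_umis)
    data.frame(
      cell_barcode = cell, n_reads = n_reads, n_umis = n_umis,
      n_phased_umis = n_phased,
      pct_phased = if (n_umis > 0) 100 * n_phased / n_umis else NA_real_,
      pct_exonic = 100 * frac(c("exonic", "utr3", "utr5")),
      pct_utr3 = 100 * frac("utr3"), pct_utr5 = 100 * frac("utr5"),
      pct_intronic = 100 * frac("intronic"),
      pct_antisense = 100 * frac("antisense"),
      pct_intergenic = 100 * frac("intergenic"),
      pct_spliced = 100 * mean(spliced[i]),
      pct_multimapper = 100 * mean(nh[i] > 1L),
      het_frac_exonic = het_frac(c("exonic", "utr3", "utr5")),
      het_frac_intronic = het_frac("intronic"),
      het_frac_antisense = het_frac("antisense"),
      het_frac_intergenic = het_frac("intergenic"),
      stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, per_cell)
  rownames(qc) <- NULL

  # reads-per-UMI distribution over filtered, feature-bearing reads
  ledger <- build_umi_ledger(stream)
  if (nrow(ledger)) {
    key <- paste(ledger$cell_barcode, ledger$feature, ledger$umi, sep = "\r")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    rpu <- data.frame(cell_barcode = parts[, 1L], feature = parts[, 2L],
                      umi = parts[, 3L], n_reads = as.integer(cnt),
                      stringsAsFactors = FALSE)
    rpu$on_target <- if (is.null(target_features)) NA else
      rpu$feature %in% target_features
  } else {
    rpu <- data.frame(cell_barcode = character(0), feature = character(0),
                      umi = character(0), n_reads = integer(0),
                      on_target = logical(0))
  }
  attr(qc, "reads_per_umi") <- rpu
  qc
}
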