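#' Construct a genotype table of heterozygous SNPs
#'
#' A genotype table holds one individual's heterozygous SNPs, indexed by
#' chromosome and 0-based position. Positions are converted from the VCF's
#' 1-based convention at parse time; all internal coordinates in this package
#' are 0-based half-open.
#'
#' @param sample_id Sample identifier.
#' @param snps A data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `phase` (one of `"REF_FIRST"` (0|1), `"ALT_FIRST"` (1|0),
#'   `"UNPHASED"` (0/1)).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sample_id, snps) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt", "phase") %in% names(snps)))
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$ref <- as.character(snps$ref)
  snps$alt <- as.character(snps$alt)
  snps$phase <- as.character(snps$phase)
  if (nrow(snps)) {
    if (any(!snps$phase %in% PHASE_LEVELS))
      stop("phase must be one of ", paste(PHASE_LEVELS, collapse = ", "))
    if (any(snps$ref == snps$alt))
      stop("ref and alt alleles must differ (het sites only)")
    key <- snp_key(snps$chrom, snps$pos)
    if (anyDuplicated(key))
      stop("at most one SNP per (chrom, pos) is allowed")
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    rownames(snps) <- snp_key(snps$chrom, snps$pos)
  }
  structure(list(sample_id = as.character(sample_id), snps = snps),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: sample '%s', %d heterozygous SNP%s on %d chromosome%s\n",
              x$sample_id, nrow(x$snps), if (nrow(x$snps) == 1) "" else "s",
              length(unique(x$snps$chrom)),
              if (length(unique(x$snps$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' Load one individual's heterozygous SNPs from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) and returns the heterozygous,
#' biallelic single-nucleotide sites for one sample. Homozygous, missing and
#' multi-allelic sites are dropped; non-SNV records (indels) are dropped with
#' a warning, since per-base read evidence is only defined for single
#' positions. Phase is taken from the genotype separator: `0|1` and `1|0`
#' record which haplotype carries the reference allele, `0/1` is unphased.
#'
#' @param vcf_path Path to the VCF file.
#' @param sample_id Sample to extract. If `NULL` and the VCF has exactly one
#'   sample, that sample is used.
#' @param require_phased If `TRUE`, an unphased heterozygous site raises an
#'   error identifying the site.
#' @return A [genotype_table()].
#' @export
load_genotypes <- function(vcf_path, sample_id = NULL, require_phased = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample_id)) {
    if (length(samples) != 1L)
      stop("sample_id required; available samples: ",
           paste(samples, collapse = ", "))
    sample_id <- samples
  }
  if (!sample_id %in% samples)
    stop(sprintf("sample '%s' not in VCF; available samples: %s",
                 sample_id, paste(samples, collapse = ", ")))
  fix <- v@fix
  gt_raw <- v@gt[, sample_id]
  # GT is the first colon-separated field per VCF spec
  gt <- sub(":.*$", "", gt_raw)
  chrom <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  non_snv <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(non_snv))
    warning(sprintf("dropped %d non-SNV record(s) (indels)", sum(non_snv)))

  het_phased <- gt %in% c("0|1", "1|0")
  het_unphased <- gt %in% c("0/1", "1/0")
  het <- (het_phased | het_unphased) & !multi & !non_snv
  if (require_phased && any(het & het_unphased)) {
    i <- which(het & het_unphased)[1L]
    stop(sprintf("unphased heterozygous site at %s:%d for sample '%s'",
                 chrom[i], pos1[i], sample_id))
  }
  phase <- rep(NA_character_, length(gt))
  phase[gt == "0|1"] <- "REF_FIRST"
  phase[gt == "1|0"] <- "ALT_FIRST"
  phase[het_unphased] <- "UNPHASED"

  keep <- which(het)
  genotype_table(sample_id,
                 data.frame(chrom = chrom[keep], pos = pos1[keep] - 1L,
                            ref = ref[keep], alt = alt[keep],
                            phase = phase[keep], stringsAsFactors = FALSE))
}

#' Heterozygous SNPs overlapping a set of intervals
#'
#' @param table A [genotype_table()].
#' @param chrom Chromosome name. An unknown chromosome yields an empty result.
#' @param blocks 0-based half-open intervals: a 2-column matrix (start, end),
#'   sorted and non-overlapping.
#' @return The rows of `table$snps` whose position lies inside any block,
#'   ordered by position.
#' @export
het_snps_overlapping <- function(table, chrom, blocks) {
  stopifnot(inherits(table, "genotype_table"))
  blocks <- as_blocks(blocks)
  snps <- table$snps[table$snps$chrom == chrom, , drop = FALSE]
  if (nrow(snps) == 0L || nrow(blocks) == 0L)
    return(snps[integer(0), , drop = FALSE])
  # positions are sorted within a chromosome: binary search per block
  idx <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    lo <- findInterval(blocks[b, 1L] - 0.5, snps$pos) + 1L
    hi <- findInterval(blocks[b, 2L] - 0.5, snps$pos)
    if (hi >= lo) idx <- c(idx, lo:hi)
  }
  snps[sort(unique(idx)), , drop = FALSE]
}

#' Call putative heterozygous SNPs from expression pileups
#'
#' Given per-site read pileups over a panel of known population SNPs, retains
#' sites with total depth `DP > 10` and alternative-allele fraction
#' `0.1 < AD/DP < 0.9` (both strict). Emitted genotypes are unphased
#' heterozygous calls: expression evidence carries no phase, so these sites
#' are usable for SNP-direct counting but not for phase-combined gene-level
#' counting.
#'
#' @param pileups A data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `dp` (total depth), `ad` (alternative-allele depth).
#' @param sample_id Identifier for the resulting table.
#' @param min_dp Depth threshold (strict `>`), default 10.
#' @param ratio_bounds Open interval for AD/DP, default `c(0.1, 0.9)`.
#' @return A [genotype_table()] with all phases `"UNPHASED"`.
#' @export
call_het_from_pileups <- function(pileups, sample_id = "called",
                                  min_dp = 10, ratio_bounds = c(0.1, 0.9)) {
  cols <- c("chrom", "pos", "ref", "alt", "dp", "ad")
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      phase = character(0), stringsAsFactors = FALSE)
  if (is.null(pileups) || nrow(pileups) == 0L)
    return(genotype_table(sample_id, empty))
  stopifnot(all(cols %in% names(pileups)))
  if (any(pileups$ad > pileups$dp) || any(pileups$ad < 0))
    stop("pileups must satisfy 0 <= ad <= dp")
  ratio <- ifelse(pileups$dp > 0, pileups$ad / pileups$dp, NA_real_)
  keep <- pileups$dp > min_dp & !is.na(ratio) &
    ratio > ratio_bounds[1L] & ratio < ratio_bounds[2L]
  kept <- pileups[keep, cols, drop = FALSE]
  kept <- kept[order(kept$chrom, kept$pos), , drop = FALSE]
  genotype_table(sample_id,
                 data.frame(chrom = kept$chrom, pos = kept$pos,
                            ref = kept$ref, alt = kept$alt,
                            phase = rep("UNPHASED", nrow(kept)),
                            stringsAsFactors = FALSE))
}

#' Write a genotype table as a VCF
#'
#' Writes a minimal VCF 4.2 file with a single sample column. Phased het
#' sites are written as `0|1`/`1|0`, unphased as `0/1`.
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  gt_of <- c(REF_FIRST = "0|1", ALT_FIRST = "1|0", UNPHASED = "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", table$sample_id, sep = "\t"))
  s <- table$snps
  rows <- if (nrow(s)) {
    paste(s$chrom, s$pos + 1L, ".", s$ref, s$alt, ".", ".", ".",
          "GT", gt_of[s$phase], sep = "\t")
  } else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
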