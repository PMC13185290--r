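#' Filter configuration for cohort-level expression filters
#'
#' Defaults follow the convention of keeping features with more than 10
#' phased UMIs in more than 5 samples (both thresholds strict).
#'
#' @param min_umis_per_sample Per-sample phased-UMI threshold (strict `>`).
#' @param min_samples Number-of-samples threshold (strict `>`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_umis_per_sample = 10L, min_samples = 5L) {
  stopifnot(min_umis_per_sample >= 0, min_samples >= 0)
  structure(list(min_umis_per_sample = as.integer(min_umis_per_sample),
                 min_samples = as.integer(min_samples)),
            class = "filter_config")
}

#' Aggregate cell-level counts into pseudobulk
#'
#' Sums the allele-resolved UMI counts of all cells from the same sample and
#' group (e.g. cell type) for each feature. Every counted cell must have
#' metadata; unknown barcodes raise an error listing them.
#'
#' @param cell_counts Count table from [count_feature_ase()] or
#'   [count_snp_level()].
#' @param cell_metadata A data.frame with a `cell_barcode` column, a `sample`
#'   column, and any further grouping columns (cell type, condition, ...).
#' @param group_cols Which metadata columns define groups (default: all
#'   metadata columns except `cell_barcode` and `sample`).
#' @return A data.frame of summed counts per (sample, groups, feature).
#' @export
pseudobulk <- function(cell_counts, cell_metadata,
                       group_cols = NULL) {
  stopifnot(all(c("cell_barcode", "sample") %in% names(cell_metadata)))
  count_cols <- intersect(c("hap1_umis", "hap2_umis", "ref_umis", "alt_umis",
                            "ambiguous_umis", "unphased_umis"),
                          names(cell_counts))
  if (nrow(cell_counts) == 0L) {
    out <- cbind(data.frame(sample = character(0)),
                 stats::setNames(
                   as.data.frame(replicate(length(count_cols), integer(0),
                                           simplify = FALSE)), count_cols),
                 data.frame(feature = character(0)))
    return(out[, c("sample", "feature", count_cols), drop = FALSE])
  }
  if (is.null(group_cols))
    group_cols <- setdiff(names(cell_metadata), c("cell_barcode", "sample"))
  m <- match(cell_counts$cell_barcode, cell_metadata$cell_barcode)
  if (anyNA(m)) {
    missing <- unique(cell_counts$cell_barcode[is.na(m)])
    stop("cells without metadata: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  keys <- cbind(data.frame(sample = cell_metadata$sample[m],
                           stringsAsFactors = FALSE),
                cell_metadata[m, group_cols, drop = FALSE],
                data.frame(feature = cell_counts$feature,
                           stringsAsFactors = FALSE))
  rownames(keys) <- NULL
  agg <- stats::aggregate(cell_counts[, count_cols, drop = FALSE],
                          by = keys, FUN = sum)
  ord <- do.call(order, agg[, c("sample", group_cols, "feature"),
                            drop = FALSE])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Orient haplotype-level gene counts at a query SNP
#'
#' Gene-level counts are labelled by haplotype (HAP1/HAP2), which is
#' arbitrary across individuals. To compare individuals, counts are oriented
#' at a chosen query SNP: samples heterozygous at the SNP keep their counts
#' with the haplotype carrying the SNP's reference allele relabelled "ref"
#' (phase `0|1`: ref = HAP1; phase `1|0`: ref = HAP2); samples not
#' heterozygous at the query SNP are excluded. Ambiguous and unphased UMIs
#' never enter the ref/alt columns. Samples whose genotype at the query SNP
#' is heterozygous but unphased cannot be oriented and are excluded by
#' default (`include_unphased = TRUE` keeps them only if you are feeding
#' SNP-direct counts that are already ref/alt-labelled).
#'
#' @param gene_counts A data.frame of per-sample counts for one feature with
#'   columns `sample`, `hap1_umis`, `hap2_umis` (plus optional
#'   `ambiguous_umis`, `unphased_umis` and grouping columns, carried
#'   through).
#' @param genotypes Named list of [genotype_table()], one per sample.
#' @param query_snp The query SNP: a list or one-row data.frame with `chrom`
#'   and `pos` (0-based).
#' @param include_unphased Keep samples with unphased het genotypes
#'   (default `FALSE`).
#' @return A data.frame (`snp`, `sample`, ..., `ref_umis`, `alt_umis`) with
#'   one row per retained (sample, input row). Empty with a warning when no
#'   sample is heterozygous at the query SNP.
#' @export
orient_gene_counts <- function(gene_counts, genotypes, query_snp,
                               include_unphased = FALSE) {
  stopifnot(all(c("sample", "hap1_umis", "hap2_umis") %in% names(gene_counts)))
  key <- snp_key(query_snp$chrom, query_snp$pos)
  rows <- list()
  for (i in seq_len(nrow(gene_counts))) {
    sm <- gene_counts$sample[i]
    gt <- genotypes[[sm]]
    if (is.null(gt)) next
    snp <- gt$snps[rownames(gt$snps) == key, , drop = FALSE]
    if (nrow(snp) == 0L) next  # not heterozygous in this sample
    phase <- snp$phase[1L]
    if (phase == "UNPHASED" && !include_unphased) next
    r <- gene_counts[i, , drop = FALSE]
    ref <- if (phase == "ALT_FIRST") r$hap2_umis else r$hap1_umis
    alt <- if (phase == "ALT_FIRST") r$hap1_umis else r$hap2_umis
    r$ref_umis <- ref
    r$alt_umis <- alt
    r$snp <- key
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0L) {
    warning(sprintf("query SNP %s is heterozygous in no sample", key))
    out <- gene_counts[integer(0), , drop = FALSE]
    out$ref_umis <- integer(0); out$alt_umis <- integer(0)
    out$snp <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$hap1_umis <- NULL
  out$hap2_umis <- NULL
  rownames(out) <- NULL
  front <- intersect(c("snp", "feature", "sample"), names(out))
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

#' Apply cohort expression filters to oriented counts
#'
#' A feature is retained iff the number of samples whose phased
#' (`ref + alt`) UMI count strictly exceeds `min_umis_per_sample` strictly
#' exceeds `min_samples`. Dropped features are reported in the `dropped`
#' attribute.
#'
#' @param oriented Long-format oriented counts with columns `sample`,
#'   `ref_umis`, `alt_umis` and a feature identifier column.
#' @param cfg A [filter_config()].
#' @param feature_col Which column identifies the feature (default: `"snp"`
#'   if present together with `"feature"`, both are combined).
#' @return The retained rows; attribute `dropped` lists dropped feature keys.
#' @export
apply_expression_filters <- function(oriented, cfg = filter_config(),
                                     feature_col = NULL) {
  stopifnot(inherits(cfg, "filter_config"),
            all(c("sample", "ref_umis", "alt_umis") %in% names(oriented)))
  if (is.null(feature_col))
    feature_col <- intersect(c("snp", "feature"), names(oriented))
  if (length(feature_col) == 0L)
    stop("no feature identifier column found")
  fkey <- do.call(paste, c(oriented[, feature_col, drop = FALSE],
                           list(sep = "\r")))
  phased <- oriented$ref_umis + oriented$alt_umis
  # count samples (not rows) exceeding the per-sample threshold
  ok_rows <- phased > cfg$min_umis_per_sample
  n_samples <- tapply(oriented$sample[ok_rows], fkey[ok_rows],
                      function(s) length(unique(s)))
  keep_keys <- names(n_samples)[n_samples > cfg$min_samples]
  keep <- fkey %in% keep_keys
  out <- oriented[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(unique(fkey), keep_keys)
  out
}

#' Downsample individuals
#'
#' Uniform sampling of samples without replacement, seed-deterministic so
#' that paired analyses (e.g. allelic imbalance vs eQTL on the same subset)
#' can reuse the identical selection. The selection can be persisted with
#' `save_to`.
#'
#' @param samples Character vector of sample ids.
#' @param n Number to select (`n <= length(samples)`).
#' @param seed Integer seed.
#' @param save_to Optional path; the selected ids are written one per line.
#' @return Character vector of selected sample ids.
#' @export
downsample_individuals <- function(samples, n, seed, save_to = NULL) {
  if (n > length(samples))
    stop(sprintf("cannot select %d of %d samples", n, length(samples)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sel <- sort(sample(samples, n))
  if (!is.null(save_to)) writeLines(sel, save_to)
  sel
}

#' Write oriented counts as a long-format TSV
#'
#' @param oriented Oriented counts from [orient_gene_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oriented_tsv <- function(oriented, path) {
  utils::write.table(oriented, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
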