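#' Construct a read observation
#'
#' A read observation is one primary alignment's barcode, UMI, feature
#' assignments, filter state, aligned blocks, and per-SNP allele evidence.
#' A "stream" is simply a list of these records.
#'
#' Votes are haplotype-coded: `HAP1`/`HAP2` name the two haplotypes of the
#' individual's phased genotype, `NEITHER` marks a covered SNP whose observed
#' base matches neither allele. The `phase` column records each SNP's own
#' phase so that downstream SNP-level counting can translate haplotype votes
#' back to reference/alternative alleles, and so that votes at unphased
#' (expression-called) SNPs can be excluded from phase-combined gene calls.
#'
#' @param qname Query (read) name.
#' @param chrom Chromosome.
#' @param cell_barcode,umi Cell barcode and UMI strings.
#' @param features Character vector of feature ids (genes, peaks or isoforms);
#'   may be empty.
#' @param n_alignments Alignment multiplicity (e.g. the `NH` tag).
#' @param wasp_pass One of `"pass"`, `"fail"`, `"not_evaluated"`. The last
#'   arises when no variant overlapped the read so the remapping filter never
#'   ran; such reads pass filters but are necessarily unphased.
#' @param blocks Aligned reference intervals, 0-based half-open, as a
#'   2-column matrix; sorted and non-overlapping.
#' @param snp_votes A data.frame with columns `snp` (SNP key), `pos`
#'   (0-based), `vote` (`"HAP1"`, `"HAP2"`, `"NEITHER"`), `phase` (the SNP's
#'   phase).
#' @param strand `"+"` or `"-"`.
#' @return A list of class `read_obs`.
#' @export
read_obs <- function(qname, chrom, cell_barcode, umi,
                     features = character(0), n_alignments = 1L,
                     wasp_pass = c("not_evaluated", "pass", "fail"),
                     blocks = NULL, snp_votes = empty_votes(),
                     strand = "+") {
  wasp_pass <- match.arg(wasp_pass)
  blocks <- as_blocks(blocks)
  if (nrow(snp_votes) && any(!snp_votes$vote %in% VOTE_LEVELS))
    stop("votes must be HAP1, HAP2 or NEITHER")
  structure(list(qname = qname, chrom = chrom, strand = strand,
                 cell_barcode = cell_barcode, umi = umi,
                 features = as.character(features),
                 n_alignments = as.integer(n_alignments),
                 wasp_pass = wasp_pass, blocks = blocks,
                 snp_votes = snp_votes),
            class = "read_obs")
}

#' Read filters for allele counting
#'
#' A read is usable for counting iff it aligned uniquely
#' (`n_alignments == 1`) and passed the mapping-bias (WASP) filter. Reads the
#' filter never evaluated (no overlapping variant) pass: they carry no allele
#' information but still count toward UMI totals.
#'
#' @param obs A [read_obs()].
#' @return `TRUE` or `FALSE`.
#' @export
passes_read_filters <- function(obs) {
  obs$n_alignments == 1L && obs$wasp_pass %in% c("pass", "not_evaluated")
}

#' Assign a read to a haplotype from its SNP votes
#'
#' A read covering several heterozygous SNPs may receive conflicting votes.
#' The read is assigned to the more common haplotype only when that haplotype
#' accounts for strictly more than 95% of the (informative) votes; otherwise
#' the read is unassigned. A read with no informative votes is unassigned
#' ("NONE", i.e. unphased).
#'
#' @param votes Character vector of votes (`"HAP1"`/`"HAP2"`; `"NEITHER"`
#'   votes carry no haplotype information and are ignored).
#' @param majority Required vote share (strict `>`), default 0.95.
#' @return `"HAP1"`, `"HAP2"` or `"NONE"`.
#' @export
read_allele_call <- function(votes, majority = 0.95) {
  votes <- votes[votes %in% c("HAP1", "HAP2")]
  n <- length(votes)
  if (n == 0L) return("NONE")
  n1 <- sum(votes == "HAP1")
  n2 <- n - n1
  if (n1 == n2) return("NONE")
  share <- max(n1, n2) / n
  if (share == 1 || share > majority) {
    if (n1 > n2) "HAP1" else "HAP2"
  } else {
    "NONE"
  }
}

# vectorized read-level calls for a list of vote vectors
read_allele_call_many <- function(vote_list, majority = 0.95) {
  vapply(vote_list, read_allele_call, character(1), majority = majority)
}

#' Build a UMI ledger from filtered reads
#'
#' One ledger row per (read, feature): the read's cell barcode, UMI, feature
#' and read-level allele call. Reads listing k features contribute k rows
#' (feature overlap is genuinely ambiguous; downstream tests are
#' per-feature). Reads failing [passes_read_filters()] are excluded; reads
#' with no feature are skipped here and appear only in QC.
#'
#' @param stream List of [read_obs()].
#' @param majority Vote-share threshold passed to [read_allele_call()].
#' @return A data.frame (`cell_barcode`, `feature`, `umi`, `call`) of class
#'   `umi_ledger`.
#' @export
build_umi_ledger <- function(stream, majority = 0.95) {
  keep <- vapply(stream, passes_read_filters, logical(1))
  stream <- stream[keep]
  nfeat <- vapply(stream, function(o) length(o$features), integer(1))
  stream <- stream[nfeat > 0L]
  nfeat <- nfeat[nfeat > 0L]
  if (length(stream) == 0L) {
    out <- data.frame(cell_barcode = character(0), feature = character(0),
                      umi = character(0), call = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("umi_ledger", "data.frame")
    return(out)
  }
  calls <- read_allele_call_many(
    lapply(stream, function(o) {
      v <- o$snp_votes
      # votes at unphased SNPs cannot be combined across SNPs into a
      # haplotype call; they are used only in SNP-direct counting
      v$vote[v$phase != "UNPHASED"]
    }), majority = majority)
  out <- data.frame(
    cell_barcode = rep(vapply(stream, `[[`, character(1), "cell_barcode"), nfeat),
    feature = unlist(lapply(stream, `[[`, "features"), use.names = FALSE),
    umi = rep(vapply(stream, `[[`, character(1), "umi"), nfeat),
    call = rep(calls, nfeat),
    stringsAsFactors = FALSE)
  class(out) <- c("umi_ledger", "data.frame")
  out
}

#' Collapse a UMI ledger to allele-resolved UMI counts
#'
#' Per (cell, feature, UMI): reads assigning both haplotypes make the UMI
#' ambiguous; reads assigning exactly one haplotype make it that haplotype
#' (unassigned reads do not dilute an informative call); a UMI with only
#' unassigned reads is unphased. Counts are aggregated per (cell, feature).
#'
#' @param ledger A ledger from [build_umi_ledger()].
#' @return A data.frame with columns `cell_barcode`, `feature`, `hap1_umis`,
#'   `hap2_umis`, `ambiguous_umis`, `unphased_umis`.
#' @export
collapse_umis <- function(ledger) {
  empty <- data.frame(cell_barcode = character(0), feature = character(0),
                      hap1_umis = integer(0), hap2_umis = integer(0),
                      ambiguous_umis = integer(0), unphased_umis = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(ledger) == 0L) return(empty)
  key <- paste(ledger$cell_barcode, ledger$feature, ledger$umi, sep = "\r")
  has1 <- tapply(ledger$call == "HAP1", key, any)
  has2 <- tapply(ledger$call == "HAP2", key, any)
  umi_cat <- ifelse(has1 & has2, "ambiguous",
                    ifelse(has1, "hap1", ifelse(has2, "hap2", "unphased")))
  parts <- do.call(rbind, strsplit(names(umi_cat), "\r", fixed = TRUE))
  cf <- paste(parts[, 1L], parts[, 2L], sep = "\r")
  tab <- table(cf, factor(umi_cat, levels = c("hap1", "hap2", "ambiguous",
                                              "unphased")))
  cf_parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(cell_barcode = cf_parts[, 1L], feature = cf_parts[, 2L],
                    hap1_umis = as.integer(tab[, "hap1"]),
                    hap2_umis = as.integer(tab[, "hap2"]),
                    ambiguous_umis = as.integer(tab[, "ambiguous"]),
                    unphased_umis = as.integer(tab[, "unphased"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_barcode, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count allele-resolved UMIs per cell and feature
#'
#' The full counting pipeline: read filters, per-read haplotype call, UMI
#' ledger, UMI collapse. Feature identity (gene, peak or isoform) only
#' changes the key space: the same rules apply whether reads are tagged with
#' genes, peaks, or isoform assignments.
#'
#' @param stream List of [read_obs()] records (e.g. from [read_tagged_sam()]
#'   or [simulate_tagged_reads()]).
#' @param genotypes Optional [genotype_table()]; when given, reads lacking
#'   votes but carrying an alignment record (long-read path) are annotated
#'   via [genotype_overlap_alleles()] first.
#' @param feature_source One of `"gene"`, `"peak"`, `"isoform"`; recorded on
#'   the result.
#' @param majority Vote-share threshold for [read_allele_call()].
#' @return A data.frame of per-(cell, feature) UMI counts; see
#'   [collapse_umis()]. Attribute `feature_source` records the key space.
#' @export
count_feature_ase <- function(stream, genotypes = NULL,
                              feature_source = c("gene", "peak", "isoform"),
                              majority = 0.95) {
  feature_source <- match.arg(feature_source)
  if (!is.null(genotypes)) {
    stream <- lapply(stream, function(o) {
      if (nrow(o$snp_votes) == 0L && !is.null(o$aln))
        o$snp_votes <- genotype_overlap_alleles(o$aln, genotypes)
      o
    })
  }
  out <- collapse_umis(build_umi_ledger(stream, majority = majority))
  attr(out, "feature_source") <- feature_source
  out
}

#' Count allele-resolved UMIs per SNP
#'
#' SNP-direct counting: each read votes independently at every heterozygous
#' SNP it covers (no cross-SNP sharing), UMIs are collapsed per
#' (cell, SNP, UMI) with the same ambiguity rule, and counts are reported as
#' reference vs alternative allele UMIs by translating haplotype votes
#' through each SNP's phase. This is the only counting mode usable with
#' unphased (e.g. expression-called) genotypes.
#'
#' @inheritParams count_feature_ase
#' @return A data.frame with columns `cell_barcode`, `feature` (the SNP key),
#'   `ref_umis`, `alt_umis`, `ambiguous_umis`, `unphased_umis`.
#' @export
count_snp_level <- function(stream, genotypes = NULL) {
  if (!is.null(genotypes)) {
    stream <- lapply(stream, function(o) {
      if (nrow(o$snp_votes) == 0L && !is.null(o$aln))
        o$snp_votes <- genotype_overlap_alleles(o$aln, genotypes)
      o
    })
  }
  keep <- vapply(stream, passes_read_filters, logical(1))
  stream <- stream[keep]
  rows <- lapply(stream, function(o) {
    v <- o$snp_votes
    if (nrow(v) == 0L) return(NULL)
    # haplotype -> ref/alt per this SNP's phase (UNPHASED stores ref as HAP1)
    call <- ifelse(v$vote == "NEITHER", "NONE",
                   ifelse((v$vote == "HAP1") == (v$phase != "ALT_FIRST"),
                          "HAP1", "HAP2"))  # HAP1 slot = reference allele
    data.frame(cell_barcode = o$cell_barcode, feature = v$snp, umi = o$umi,
               call = call, stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, rows)
  if (is.null(ledger))
    ledger <- data.frame(cell_barcode = character(0), feature = character(0),
                         umi = character(0), call = character(0),
                         stringsAsFactors = FALSE)
  class(ledger) <- c("umi_ledger", "data.frame")
  out <- collapse_umis(ledger)
  names(out)[names(out) == "hap1_umis"] <- "ref_umis"
  names(out)[names(out) == "hap2_umis"] <- "alt_umis"
  out
}

#' Downsample an alignment stream
#'
#' Keeps each read independently with the given probability. All records
#' sharing a query name are kept or dropped together, and a fixed seed yields
#' an identical subset.
#'
#' @param stream List of [read_obs()].
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return The downsampled stream (a list).
#' @export
downsample_stream <- function(stream, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  if (fraction == 1) return(stream)
  qnames <- vapply(stream, `[[`, character(1), "qname")
  uq <- sort(unique(qnames))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  keep_q <- uq[stats::runif(length(uq)) < fraction]
  stream[qnames %in% keep_q]
}

#' Read a tagged SAM/BAM file into a stream of read observations
#'
#' Reads a coordinate-sorted SAM or BAM file whose records carry the cell
#' barcode, UMI, feature, alignment-multiplicity and (for the short-read
#' path) per-read variant tags emitted by a WASP-aware aligner. Secondary and
#' supplementary records are dropped: multiplicity is judged from the `NH`
#' tag, not record multiplicity.
#'
#' The default tag dialect: cell barcode `CB`, UMI `UB`, feature `GN` (gene;
#' use `PK` for peaks or `XT` for isoforms), multiplicity `NH`, variant votes
#' `vA` (byte array: 1 = haplotype 1, 2 = haplotype 2, 3 = neither), variant
#' positions `vG` (0-based reference positions, parallel to `vA`), WASP
#' status `vW` (1 = pass; other values = fail; absent = not evaluated).
#'
#' @param path SAM or BAM file.
#' @param genotypes Optional [genotype_table()] used to attach each vote's
#'   SNP phase; without it votes are assumed to be at phased sites
#'   (`REF_FIRST` keys are synthesized from position alone).
#' @param feature_tag Which tag holds the feature (default `"GN"`).
#' @param tags Named list overriding the tag dialect entries `cb`, `ub`,
#'   `nh`, `va`, `vg`, `vw`.
#' @param keep_seq Keep query sequence/CIGAR (long-read path) in an `aln`
#'   field on each record.
#' @return A list of [read_obs()] records.
#' @export
read_tagged_sam <- function(path, genotypes = NULL, feature_tag = "GN",
                            tags = list(), keep_seq = FALSE) {
  dialect <- utils::modifyList(
    list(cb = "CB", ub = "UB", nh = "NH", va = "vA", vg = "vG", vw = "vW",
         as = "AS"), tags)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"),
    tag = unique(c(unlist(dialect, use.names = FALSE), feature_tag)),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (n == 0L) return(list())
  tg <- x$tag
  get_tag <- function(nm, default) {
    v <- tg[[nm]]
    if (is.null(v)) rep(default, n) else v
  }
  cb <- get_tag(dialect$cb, NA_character_)
  ub <- get_tag(dialect$ub, NA_character_)
  nh <- get_tag(dialect$nh, 1L)
  vw <- get_tag(dialect$vw, NA_integer_)
  feat <- get_tag(feature_tag, NA_character_)
  va <- tg[[dialect$va]]
  vg <- tg[[dialect$vg]]
  scores <- get_tag(dialect$as, NA_integer_)

  block_ranges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    x$cigar, pos = x$pos, ops = c("M", "=", "X"), reduce.ranges = TRUE)

  lapply(seq_len(n), function(i) {
    chrom <- as.character(x$rname[i])
    votes <- empty_votes()
    if (!is.null(va) && !is.null(va[[i]]) && length(va[[i]])) {
      pos0 <- as.integer(vg[[i]])
      vote <- c("HAP1", "HAP2", "NEITHER")[as.integer(va[[i]])]
      phase <- rep("REF_FIRST", length(pos0))
      key <- snp_key(rep(chrom, length(pos0)), pos0)
      if (!is.null(genotypes)) {
        hit <- match(key, rownames(genotypes$snps))
        phase[!is.na(hit)] <- genotypes$snps$phase[hit[!is.na(hit)]]
      }
      votes <- data.frame(snp = key, pos = pos0, vote = vote, phase = phase,
                          stringsAsFactors = FALSE)
    }
    wasp <- if (is.na(vw[i])) "not_evaluated" else if (vw[i] == 1L) "pass" else "fail"
    ir <- block_ranges[[i]]
    obs <- read_obs(
      qname = x$qname[i], chrom = chrom,
      cell_barcode = cb[i], umi = ub[i],
      features = split_feature_tag(feat[i]),
      n_alignments = if (is.na(nh[i])) 1L else nh[i],
      wasp_pass = wasp, blocks = iranges_to_blocks(ir),
      snp_votes = votes, strand = as.character(x$strand[i]))
    if (keep_seq) {
      obs$aln <- list(qname = x$qname[i], chrom = chrom, pos = x$pos[i],
                      cigar = x$cigar[i], seq = as.character(x$seq[i]),
                      strand = as.character(x$strand[i]),
                      score = scores[i])
    }
    obs
  })
}

#' Write allele-resolved counts as TSV and sparse-triplet files
#'
#' @param counts A count table from [count_feature_ase()] or
#'   [count_snp_level()].
#' @param path Output TSV path. With `sparse = TRUE`, also writes
#'   `<path>.mtx`-style triplet files (`barcodes.tsv`, `features.tsv`, and
#'   one MatrixMarket file per count category) next to it.
#' @param sparse Also export sparse triplets.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, sparse = FALSE) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sparse && nrow(counts)) {
    dir <- dirname(path)
    cells <- sort(unique(counts$cell_barcode))
    feats <- sort(unique(counts$feature))
    writeLines(cells, file.path(dir, "barcodes.tsv"))
    writeLines(feats, file.path(dir, "features.tsv"))
    count_cols <- setdiff(names(counts), c("cell_barcode", "feature"))
    for (cc in count_cols) {
      keep <- counts[[cc]] > 0L
      mm <- file.path(dir, paste0(sub("\\.tsv$", "", basename(path)),
                                  ".", cc, ".mtx"))
      lines <- c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", length(feats), length(cells), sum(keep)),
                 sprintf("%d %d %d",
                         match(counts$feature[keep], feats),
                         match(counts$cell_barcode[keep], cells),
                         counts[[cc]][keep]))
      writeLines(lines, mm)
    }
  }
  invisible(path)
}
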