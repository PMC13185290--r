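#' Build an isoform index from a GTF annotation
#'
#' Creates one spliced isoform model per transcript (its exon blocks) and one
#' unspliced isoform model per gene spanning the whole gene body — a
#' pre-mRNA-like transcript including introns. Isoform ids are the transcript
#' id joined with the gene id; unspliced models are `<gene_id>_unspliced`.
#' Transcripts with no exon records are skipped with a warning.
#'
#' @param gtf Path to a GTF file or an imported `GRanges`.
#' @return A list of class `isoform_index` with elements `spans` (a `GRanges`
#'   of isoform extents with `isoform_id`, `gene_id`, `is_unspliced`) and
#'   `exons` (named list: isoform_id -> 0-based half-open block matrix).
#' @export
build_isoform_index <- function(gtf) {
  gr <- import_gtf(gtf)
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  tx <- gr[type == "transcript"]
  if (length(tx) && length(ex)) {
    missing_ex <- setdiff(tx$transcript_id, ex$transcript_id)
    if (length(missing_ex))
      warning(sprintf("skipped %d transcript(s) with no exons: %s",
                      length(missing_ex),
                      paste(utils::head(missing_ex, 5), collapse = ", ")))
  }
  exons <- list()
  span_chrom <- character(0); span_start <- integer(0); span_end <- integer(0)
  span_strand <- character(0); span_id <- character(0); span_gene <- character(0)
  span_unspliced <- logical(0)

  if (length(ex)) {
    by_tx <- split(seq_along(ex), ex$transcript_id)
    for (tid in names(by_tx)) {
      e <- ex[by_tx[[tid]]]
      gid <- as.character(e$gene_id[1L])
      iso <- paste(tid, gid, sep = "_")
      ir <- IRanges::reduce(IRanges::ranges(e))
      exons[[iso]] <- iranges_to_blocks(ir)
      span_chrom <- c(span_chrom, as.character(GenomicRanges::seqnames(e)[1L]))
      span_start <- c(span_start, min(IRanges::start(ir)))
      span_end <- c(span_end, max(IRanges::end(ir)))
      span_strand <- c(span_strand, as.character(BiocGenerics::strand(e)[1L]))
      span_id <- c(span_id, iso)
      span_gene <- c(span_gene, gid)
      span_unspliced <- c(span_unspliced, FALSE)
    }
  }
  genes <- gr[type == "gene"]
  if (length(genes) == 0L && length(ex)) {
    g <- unlist(range(S4Vectors::split(ex, ex$gene_id)))
    genes <- g
    genes$gene_id <- names(g)
  }
  for (i in seq_along(genes)) {
    gid <- as.character(genes$gene_id[i])
    iso <- paste(gid, "unspliced", sep = "_")
    st <- IRanges::start(genes)[i]; en <- IRanges::end(genes)[i]
    exons[[iso]] <- as_blocks(cbind(st - 1L, en))
    span_chrom <- c(span_chrom, as.character(GenomicRanges::seqnames(genes)[i]))
    span_start <- c(span_start, st)
    span_end <- c(span_end, en)
    span_strand <- c(span_strand, as.character(BiocGenerics::strand(genes)[i]))
    span_id <- c(span_id, iso)
    span_gene <- c(span_gene, gid)
    span_unspliced <- c(span_unspliced, TRUE)
  }
  spans <- if (length(span_id)) {
    GenomicRanges::GRanges(span_chrom,
                           IRanges::IRanges(span_start, span_end),
                           strand = span_strand, isoform_id = span_id,
                           gene_id = span_gene, is_unspliced = span_unspliced)
  } else GenomicRanges::GRanges()
  structure(list(spans = spans, exons = exons), class = "isoform_index")
}

#' Merge nearby aligned blocks of a read
#'
#' Fuses adjacent blocks whose inter-block gap is at most `gap` base pairs
#' (long reads carry small indels that fragment their aligned blocks). The
#' operation is idempotent.
#'
#' @param blocks 0-based half-open block matrix, sorted by start.
#' @param gap Maximum gap to fuse, default 10 bp.
#' @return A merged block matrix.
#' @export
merge_read_blocks <- function(blocks, gap = 10L) {
  blocks <- as_blocks(blocks)
  if (nrow(blocks) <= 1L) return(blocks)
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  ir <- IRanges::reduce(blocks_to_iranges(blocks), min.gapwidth = gap + 1L)
  iranges_to_blocks(ir)
}

#' Keep only the best-scoring alignment per read
#'
#' For each query, keeps the alignment with the strictly maximum alignment
#' score; a read whose maximum score is attained by more than one alignment
#' is discarded entirely.
#'
#' @param alignments List of alignment records, each a list with at least
#'   `qname` and `score`.
#' @return The filtered list (at most one record per query).
#' @export
best_alignment_filter <- function(alignments) {
  if (length(alignments) == 0L) return(alignments)
  qn <- vapply(alignments, `[[`, character(1), "qname")
  sc <- vapply(alignments, function(a) as.numeric(a$score), numeric(1))
  keep <- logical(length(alignments))
  for (q in unique(qn)) {
    i <- which(qn == q)
    mx <- max(sc[i])
    best <- i[sc[i] == mx]
    if (length(best) == 1L) keep[best] <- TRUE
  }
  alignments[keep]
}

#' Assign a long read to an isoform
#'
#' Candidates are the isoforms whose genomic span overlaps the read's span.
#' Each candidate's exon blocks are trimmed to the read's span, and the
#' overlap is the total intersected length between the trimmed exon blocks
#' and the (merged) read blocks. A candidate survives only when the overlap
#' reaches 95% of the trimmed-isoform covered length *and* 95% of the read
#' covered length. (With `require_both = FALSE`, reaching 95% of either
#' denominator suffices; under that lax variant any spliced read ties with
#' its gene's unspliced model — which always contains the read's blocks —
#' and is discarded by the margin rule, so the strict variant is the
#' default.) Among survivors the largest overlap wins, but if any other
#' survivor's overlap is within (strictly less than) 10 bp of the largest —
#' including exact ties — the read is unassignable.
#'
#' @param read_blocks Merged 0-based half-open block matrix
#'   (see [merge_read_blocks()]).
#' @param index An [build_isoform_index()] object.
#' @param chrom Chromosome of the read.
#' @param min_frac Overlap fraction threshold, default 0.95.
#' @param margin Runner-up margin in bp, default 10.
#' @param require_both Require `min_frac` on both denominators (default
#'   `TRUE`; `FALSE` keeps a candidate that reaches 95% of either).
#' @return The winning isoform id, or `NA_character_` for no assignment.
#' @export
assign_isoform <- function(read_blocks, index, chrom, min_frac = 0.95,
                           margin = 10L, require_both = TRUE) {
  read_blocks <- as_blocks(read_blocks)
  if (nrow(read_blocks) == 0L) return(NA_character_)
  read_span <- c(min(read_blocks[, 1L]), max(read_blocks[, 2L]))
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(read_span[1L] + 1L, read_span[2L]))
  hits <- GenomicRanges::findOverlaps(q, index$spans, ignore.strand = TRUE)
  cand <- index$spans$isoform_id[S4Vectors::subjectHits(hits)]
  if (length(cand) == 0L) return(NA_character_)
  read_cov <- blocks_width(read_blocks)

  ov <- numeric(0); ids <- character(0)
  for (iso in cand) {
    eb <- index$exons[[iso]]
    # trim exon blocks to the read's genomic span
    tb <- cbind(pmax(eb[, 1L], read_span[1L]), pmin(eb[, 2L], read_span[2L]))
    tb <- tb[tb[, 1L] < tb[, 2L], , drop = FALSE]
    if (nrow(tb) == 0L) next
    tb <- as_blocks(tb)
    iso_cov <- blocks_width(tb)
    o <- blocks_intersect_width(tb, read_blocks)
    ok_iso <- o >= min_frac * iso_cov
    ok_read <- o >= min_frac * read_cov
    keep <- if (require_both) ok_iso && ok_read else ok_iso || ok_read
    if (keep) {
      ov <- c(ov, o)
      ids <- c(ids, iso)
    }
  }
  if (length(ids) == 0L) return(NA_character_)
  best <- max(ov)
  # discard if any *other* surviving isoform is < margin bp shorter
  # (ties have difference 0 < margin, hence are discarded too)
  if (sum(best - ov < margin) > 1L) return(NA_character_)
  ids[which.max(ov)]
}

# walk a CIGAR to map reference positions -> query positions (0-based).
# Returns a function(ref_pos0) -> query index (1-based into seq) or NA.
ref_to_query_map <- function(cigar, pos1) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  ref_starts <- integer(0); ref_ends <- integer(0); q_starts <- integer(0)
  rp <- pos1 - 1L  # 0-based reference cursor
  qp <- 0L         # 0-based query cursor
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      ref_starts <- c(ref_starts, rp)
      ref_ends <- c(ref_ends, rp + len)
      q_starts <- c(q_starts, qp)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    } # H, P consume neither
  }
  function(ref_pos0) {
    i <- which(ref_pos0 >= ref_starts & ref_pos0 < ref_ends)
    if (length(i) == 0L) return(NA_integer_)
    q_starts[i[1L]] + (ref_pos0 - ref_starts[i[1L]]) + 1L
  }
}

#' Derive per-SNP allele votes by direct genotype lookup
#'
#' For the long-read path no aligner-provided variant annotation exists;
#' instead, for each heterozygous SNP inside the read's aligned blocks, the
#' query base at that reference position is compared to the SNP's alleles.
#' The reference base votes for the haplotype carrying the reference allele
#' (per the SNP's phase), the alternative base for the other haplotype, and
#' any third base — or a position deleted/skipped in the read — yields a
#' `NEITHER` vote. Only an aligned query base is evidence.
#'
#' @param aln Alignment record: a list with `chrom`, `pos` (1-based leftmost
#'   mapped position), `cigar`, `seq` (query sequence).
#' @param genotypes A [genotype_table()].
#' @return A `snp_votes` data.frame (see [read_obs()]).
#' @export
genotype_overlap_alleles <- function(aln, genotypes) {
  # segments fused across deletions (but not across intron skips): a SNP
  # under a small deletion is "covered" by the read and votes NEITHER,
  # while SNPs under N gaps are simply not covered
  segments <- iranges_to_blocks(IRanges::reduce(
    GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar, pos = aln$pos, ops = c("M", "=", "X", "D"))[[1L]],
    min.gapwidth = 1L))
  snps <- het_snps_overlapping(genotypes, aln$chrom, segments)
  if (nrow(snps) == 0L) return(empty_votes())
  qmap <- ref_to_query_map(aln$cigar, aln$pos)
  bases <- strsplit(aln$seq, "")[[1L]]
  vote <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    qi <- qmap(snps$pos[i])
    b <- if (is.na(qi) || qi > length(bases)) NA_character_ else bases[qi]
    vote[i] <- if (is.na(b)) {
      "NEITHER"
    } else if (b == snps$ref[i]) {
      if (snps$phase[i] == "ALT_FIRST") "HAP2" else "HAP1"
    } else if (b == snps$alt[i]) {
      if (snps$phase[i] == "ALT_FIRST") "HAP1" else "HAP2"
    } else {
      "NEITHER"
    }
  }
  data.frame(snp = snp_key(snps$chrom, snps$pos), pos = snps$pos,
             vote = vote, phase = snps$phase, stringsAsFactors = FALSE)
}

#' Alignment error statistics from a CIGAR string
#'
#' Counts sequence-matched base pairs (`=` operations), substitutions (`X`),
#' inserted and deleted bases, and reports per-matched-base rates. Generic
#' `M` operations do not distinguish match from mismatch; they are resolved
#' through the MD tag when supplied, otherwise an error is raised.
#'
#' @param cigar CIGAR string.
#' @param md Optional MD tag value for resolving generic `M` operations.
#' @return A list of class `cigar_stats`: `matched_bp`, `mismatches`,
#'   `insertions`, `deletions` and the corresponding `*_rate` fields.
#' @export
cigar_error_stats <- function(cigar, md = NULL) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  n_eq <- sum(lens[ops == "="])
  n_x <- sum(lens[ops == "X"])
  n_m <- sum(lens[ops == "M"])
  ins <- sum(lens[ops == "I"])
  del <- sum(lens[ops == "D"])
  if (n_m > 0L) {
    if (is.null(md))
      stop("cannot resolve substitutions: CIGAR has generic 'M' operations ",
           "and no MD tag was supplied")
    # MD: numbers = matching run lengths, letters = substituted reference
    # bases, ^<seq> = deletion (not a substitution)
    toks <- regmatches(md, gregexpr("\\^[A-Za-z]+|[A-Za-z]|[0-9]+", md))[[1L]]
    subs <- sum(grepl("^[A-Za-z]$", toks))
    n_x <- n_x + subs
    n_eq <- n_eq + n_m - subs
  }
  matched <- n_eq
  rate <- function(x) if (matched > 0L) x / matched else NA_real_
  structure(list(matched_bp = matched, mismatches = n_x,
                 insertions = ins, deletions = del,
                 mismatch_rate = rate(n_x), insertion_rate = rate(ins),
                 deletion_rate = rate(del)),
            class = "cigar_stats")
}

#' Number of mapped base pairs of an alignment
#'
#' The count of aligned bases consuming both reference and query (`M`, `=`,
#' `X` operations); clipping, intron skips and indels are excluded.
#'
#' @param cigar CIGAR string.
#' @return Integer bp count.
#' @export
mapped_length <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  sum(lens[ops %in% c("M", "=", "X")])
}

#' Annotate long-read alignments with isoform assignments
#'
#' Applies [best_alignment_filter()], merges each surviving alignment's
#' blocks, assigns it to an isoform with [assign_isoform()], and returns only
#' assigned reads, each with the isoform id in its `features` field (the
#' `XT`-tag convention). The result feeds [count_feature_ase()] with
#' `feature_source = "isoform"`.
#'
#' @param alignments List of alignment records (`qname`, `chrom`, `pos`,
#'   `cigar`, `seq`, `score`, `cell_barcode`, `umi`).
#' @param index An [build_isoform_index()] object.
#' @param genotypes Optional [genotype_table()] to attach allele votes via
#'   [genotype_overlap_alleles()].
#' @param ... Passed to [assign_isoform()].
#' @return A list of [read_obs()] with `features` = assigned isoform id.
#' @export
assign_isoforms_stream <- function(alignments, index, genotypes = NULL, ...) {
  alignments <- best_alignment_filter(alignments)
  out <- list()
  for (a in alignments) {
    blocks <- merge_read_blocks(iranges_to_blocks(
      GenomicAlignments::cigarRangesAlongReferenceSpace(
        a$cigar, pos = a$pos, ops = c("M", "=", "X"),
        reduce.ranges = TRUE)[[1L]]))
    iso <- assign_isoform(blocks, index, a$chrom, ...)
    if (is.na(iso)) next
    votes <- if (is.null(genotypes)) empty_votes() else
      genotype_overlap_alleles(a, genotypes)
    obs <- read_obs(qname = a$qname, chrom = a$chrom,
                    cell_barcode = a$cell_barcode %||% NA_character_,
                    umi = a$umi %||% NA_character_,
                    features = iso, n_alignments = 1L,
                    wasp_pass = "not_evaluated", blocks = blocks,
                    snp_votes = votes, strand = a$strand %||% "+")
    obs$aln <- a
    out <- c(out, list(obs))
  }
  out
}
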