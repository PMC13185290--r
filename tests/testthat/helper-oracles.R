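# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops,
# no interval structures, no ledgers.

# naive allele counting: materialize every read, apply the three rules
# (filter, >95% majority call, per-UMI ambiguity) with explicit loops
oracle_count_feature <- function(stream, majority = 0.95) {
  calls <- list()
  for (o in stream) {
    if (o$n_alignments != 1L) next
    if (o$wasp_pass == "fail") next
    v <- o$snp_votes
    v <- v$vote[v$phase != "UNPHASED"]
    n1 <- sum(v == "HAP1"); n2 <- sum(v == "HAP2")
    call <- "NONE"
    if (n1 + n2 > 0 && n1 != n2) {
      share <- max(n1, n2) / (n1 + n2)
      if (share > majority || share == 1)
        call <- if (n1 > n2) "HAP1" else "HAP2"
    }
    for (f in o$features) {
      key <- paste(o$cell_barcode, f, o$umi, sep = "\t")
      calls[[key]] <- c(calls[[key]], call)
    }
  }
  agg <- list()
  for (key in names(calls)) {
    cs <- calls[[key]]
    cat_ <- if (any(cs == "HAP1") && any(cs == "HAP2")) "ambiguous"
    else if (any(cs == "HAP1")) "hap1"
    else if (any(cs == "HAP2")) "hap2"
    else "unphased"
    parts <- strsplit(key, "\t", fixed = TRUE)[[1L]]
    cf <- paste(parts[1L], parts[2L], sep = "\t")
    if (is.null(agg[[cf]]))
      agg[[cf]] <- c(hap1 = 0L, hap2 = 0L, ambiguous = 0L, unphased = 0L)
    agg[[cf]][cat_] <- agg[[cf]][cat_] + 1L
  }
  if (length(agg) == 0L)
    return(data.frame(cell_barcode = character(0), feature = character(0),
                      hap1_umis = integer(0), hap2_umis = integer(0),
                      ambiguous_umis = integer(0), unphased_umis = integer(0),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(agg), "\t", fixed = TRUE))
  m <- do.call(rbind, agg)
  out <- data.frame(cell_barcode = parts[, 1L], feature = parts[, 2L],
                    hap1_umis = unname(m[, "hap1"]),
                    hap2_umis = unname(m[, "hap2"]),
                    ambiguous_umis = unname(m[, "ambiguous"]),
                    unphased_umis = unname(m[, "unphased"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_barcode, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive isoform assignment: explicit loops over all isoforms and per-base
# position sets instead of interval arithmetic
oracle_assign_isoform <- function(read_blocks, index, chrom,
                                  min_frac = 0.95, margin = 10L,
                                  require_both = TRUE) {
  read_pos <- integer(0)
  for (b in seq_len(nrow(read_blocks)))
    read_pos <- c(read_pos, seq(read_blocks[b, 1L], read_blocks[b, 2L] - 1L))
  rs <- min(read_pos); re <- max(read_pos)
  iso_chrom <- as.character(GenomicRanges::seqnames(index$spans))
  ids <- character(0); ov <- numeric(0)
  for (i in seq_along(index$spans)) {
    if (iso_chrom[i] != chrom) next
    iso <- index$spans$isoform_id[i]
    eb <- index$exons[[iso]]
    span_s <- min(eb[, 1L]); span_e <- max(eb[, 2L])
    if (span_e <= rs || span_s > re) next  # span overlap with read span
    iso_pos <- integer(0)
    for (b in seq_len(nrow(eb)))
      iso_pos <- c(iso_pos, seq(eb[b, 1L], eb[b, 2L] - 1L))
    iso_pos <- iso_pos[iso_pos >= rs & iso_pos <= re]  # trim to read span
    if (length(iso_pos) == 0L) next
    o <- length(intersect(iso_pos, read_pos))
    ok_iso <- o >= min_frac * length(iso_pos)
    ok_read <- o >= min_frac * length(read_pos)
    keep <- if (require_both) ok_iso && ok_read else ok_iso || ok_read
    if (keep) { ids <- c(ids, iso); ov <- c(ov, o) }
  }
  if (length(ids) == 0L) return(NA_character_)
  best <- max(ov)
  if (sum(best - ov < margin) > 1L) return(NA_character_)
  ids[which.max(ov)]
}

# naive coverage: per-base depth array
oracle_coverage_regions <- function(intervals, min_cov = 10L) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    d <- intervals[intervals$chrom == ch, , drop = FALSE]
    len <- max(d$end)
    depth <- integer(len)
    for (i in seq_len(nrow(d)))
      depth[(d$start[i] + 1L):d$end[i]] <-
        depth[(d$start[i] + 1L):d$end[i]] + 1L
    r <- rle(depth >= min_cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[j] - 1L, end = ends[j],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# mixed true allelic ratios for the calibration design (some balanced, some
# imbalanced features)
mixed_true_ratios <- function(seed, n = 200L) {
  set.seed(seed)
  stats::runif(n, 0.3, 0.7)
}

# quick builder for hand fixtures
mk_read <- function(qname, cell, umi, features, votes = character(0),
                    nh = 1L, wasp = NULL, chrom = "chrS",
                    blocks = cbind(100L, 200L), phase = NULL) {
  sv <- if (length(votes)) {
    data.frame(snp = sprintf("%s:%d", chrom, seq_along(votes) + 100L),
               pos = seq_along(votes) + 100L, vote = votes,
               phase = if (is.null(phase)) rep("REF_FIRST", length(votes))
               else rep_len(phase, length(votes)),
               stringsAsFactors = FALSE)
  } else alleleflow:::empty_votes()
  if (is.null(wasp)) wasp <- if (length(votes)) "pass" else "not_evaluated"
  read_obs(qname = qname, chrom = chrom, cell_barcode = cell, umi = umi,
           features = features, n_alignments = nh, wasp_pass = wasp,
           blocks = blocks, snp_votes = sv)
}
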