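`%||%` <- function(a, b) if (is.null(a)) b else a

# Phase codes for a heterozygous genotype: which haplotype carries the
# reference allele. REF_FIRST = "0|1", ALT_FIRST = "1|0", UNPHASED = "0/1".
PHASE_LEVELS <- c("REF_FIRST", "ALT_FIRST", "UNPHASED")
VOTE_LEVELS  <- c("HAP1", "HAP2", "NEITHER")

#' @noRd
snp_key <- function(chrom, pos) sprintf("%s:%d", chrom, as.integer(pos))

# blocks are 0-based half-open intervals as a 2-column matrix (start, end)
as_blocks <- function(x) {
  if (is.null(x)) return(matrix(integer(0), ncol = 2L,
                                dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  if (any(m[, 2L] <= m[, 1L])) stop("blocks must have start < end")
  m
}

blocks_to_iranges <- function(blocks) {
  IRanges::IRanges(start = blocks[, 1L] + 1L, end = blocks[, 2L])
}

iranges_to_blocks <- function(ir) {
  as_blocks(cbind(IRanges::start(ir) - 1L, IRanges::end(ir)))
}

# total bp covered by a block set (blocks assumed disjoint)
blocks_width <- function(blocks) sum(blocks[, 2L] - blocks[, 1L])

# intersection length of two disjoint sorted block sets
blocks_intersect_width <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ov <- IRanges::intersect(blocks_to_iranges(a), blocks_to_iranges(b))
  sum(IRanges::width(ov))
}

split_feature_tag <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  unlist(strsplit(x, "[;,]"), use.names = FALSE)
}

empty_votes <- function() {
  data.frame(snp = character(0), pos = integer(0), vote = character(0),
             phase = character(0), stringsAsFactors = FALSE)
}

import_gtf <- function(gtf) {
  if (!is.character(gtf)) return(gtf)
  # rtracklayer chokes on files with no records at all
  has_data <- any(!grepl("^#|^$", readLines(gtf)))
  if (!has_data) {
    gr <- GenomicRanges::GRanges()
    gr$type <- character(0)
    return(gr)
  }
  rtracklayer::import(gtf, format = "gtf")
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name))
}
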