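#' Extend intervals in the 3' direction
#'
#' Read-evidence intervals from 3'-biased libraries are extended toward the
#' transcript 3' end before merging: `+`-strand intervals grow at their end,
#' `-`-strand intervals at their start (floored at the chromosome start).
#'
#' @param intervals A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @param bp Extension length, default 200.
#' @return The extended intervals.
#' @export
extend_3prime <- function(intervals, bp = 200L) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(intervals)))
  out <- intervals
  plus <- out$strand == "+"
  out$end[plus] <- out$end[plus] + bp
  out$start[!plus] <- pmax(out$start[!plus] - bp, 0L)
  out
}

#' Maximal regions covered by at least a minimum number of intervals
#'
#' Sweep-line coverage: emits the maximal runs of positions covered by at
#' least `min_cov` input intervals ("at least", i.e. `>=`).
#'
#' @param intervals A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); order is irrelevant.
#' @param min_cov Coverage threshold, default 10.
#' @return A data.frame (`chrom`, `start`, `end`) of disjoint regions,
#'   sorted by chromosome and start.
#' @export
coverage_regions <- function(intervals, min_cov = 10L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(intervals) == 0L) return(empty)
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    d <- intervals[intervals$chrom == ch, , drop = FALSE]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = d$start + 1L, end = d$end))
    runs <- IRanges::slice(cov, lower = min_cov, rangesOnly = TRUE)
    if (length(runs))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(runs) - 1L,
        end = IRanges::end(runs), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merged flank regions around heterozygous SNPs
#'
#' Each SNP contributes a region of `flank` bp on either side of (and
#' including) the SNP base — width `2 * flank + 1` — clipped at the
#' chromosome start; overlapping or adjacent regions are merged.
#'
#' @param snps A data.frame with columns `chrom` and `pos` (0-based), e.g.
#'   the `snps` element of a [genotype_table()].
#' @param flank Flank size in bp, default 130.
#' @return A data.frame (`chrom`, `start`, `end`), 0-based half-open,
#'   merged and sorted.
#' @export
snp_flank_regions <- function(snps, flank = 130L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.null(snps) || nrow(snps) == 0L) return(empty)
  out <- list()
  for (ch in sort(unique(snps$chrom))) {
    pos <- snps$pos[snps$chrom == ch]
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(pos - flank, 0L) + 1L, end = pos + flank + 1L))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write BED interval files
#'
#' Plain 0-based half-open BED; `read_bed` accepts 3+ columns (strand taken
#' from column 6 when present), `write_bed` emits 3 or 6 columns.
#'
#' @param path File path.
#' @return `read_bed`: a data.frame with `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- data.frame(chrom = d[[1L]], start = as.integer(d[[2L]]),
                    end = as.integer(d[[3L]]), stringsAsFactors = FALSE)
  if (ncol(d) >= 6L) out$strand <- d[[6L]]
  out
}

#' @param intervals Intervals to write (`chrom`, `start`, `end`, optional
#'   `strand` written in 6-column form).
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  if ("strand" %in% names(intervals)) {
    d <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    ".", 0L, intervals$strand)
  } else {
    d <- data.frame(intervals$chrom, intervals$start, intervals$end)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
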