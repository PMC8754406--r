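#' Genomic coordinate convention conversion
#'
#' All internal coordinates in this package are 0-based half-open
#' \code{[start, end)}; GFF3 uses 1-based inclusive \code{start..end}.
#' These two helpers convert between the conventions at the I/O boundary
#' and are the single place the off-by-one lives.
#'
#' @param start,end interval bounds in the source convention.
#' @return A two-column data.frame with the converted \code{start} and
#'   \code{end}.
#' @examples
#' gffToZeroBased(100, 200)   # -> [99, 200), length 101
#' zeroBasedToGff(99, 200)    # -> 100..200
#' @export
gffToZeroBased <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = start - 1, end = end)
}

#' @rdname gffToZeroBased
#' @export
zeroBasedToGff <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  data.frame(start = start + 1, end = end)
}

# GRanges (1-based) for the CDS intervals of a list of GeneModel, with a
# gene index in mcols. Internal helper shared by mask building and counting.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
genesToGRanges <- function(genes) {
  n <- vapply(genes, function(g) length(g@cdsStarts), integer(1))
  GenomicRanges::GRanges(
    seqnames = rep(vapply(genes, function(g) g@chrom, character(1)), n),
    ranges = IRanges::IRanges(
      start = unlist(lapply(genes, function(g) g@cdsStarts)) + 1,
      end = unlist(lapply(genes, function(g) g@cdsEnds))),
    strand = rep(vapply(genes, function(g) g@strand, character(1)), n),
    geneIdx = rep(seq_along(genes), n))
}
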