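#' Tile sliding or non-overlapping windows over a genome layout
#'
#' For each chromosome of length `L`, windows start every `step` bp while the
#' start is inside the chromosome, each of width `size` truncated at the
#' chromosome end. With `step == size` this is a non-overlapping tiling;
#' every base of every chromosome is covered at least once whenever
#' `step <= size`. The 100-kb/10-kb sliding configuration used for
#' chromosome-scale heterozygosity paintings is `tileWindows(layout, 1e5,
#' 1e4)`.
#'
#' @param layout a `Seqinfo` genome layout.
#' @param size window width in bp.
#' @param step distance between window starts in bp; must satisfy
#'   `0 < step <= size`.
#' @return A `GRanges` of windows, ordered by chromosome then start.
#' @examples
#' tileWindows(genomeLayout("chr1", 250000), size = 1e5, step = 1e4)
#' @export
tileWindows <- function(layout, size, step = size) {
  size <- as.numeric(size); step <- as.numeric(step)
  if (step <= 0 || size <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed size")
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  per <- lapply(seq_along(chroms), function(i) {
    L <- lens[i]
    start0 <- seq(0, L - 1, by = step)
    GenomicRanges::GRanges(chroms[i],
                           IRanges::IRanges(start = start0 + 1,
                                            end = pmin(start0 + size, L)),
                           seqinfo = layout)
  })
  do.call(c, per)
}
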