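#' Per-window heterozygosity track for one sample
#'
#' Counts, in each window, the sites where the sample's genotype carries two
#' distinct allele indices. A site at 1-based position p belongs to a window
#' iff p lies within it (windows are GRanges; on disk BED output is 0-based
#' half-open). Missing genotypes are never counted as heterozygous; when a
#' callability `mask` is supplied the window denominator is the masked window
#' length minus the missing sites in the window, otherwise it is the full
#' window length.
#'
#' @param x a [VariantPanel-class].
#' @param sample sample id.
#' @param windows GRanges of windows, e.g. from [tileWindows()].
#' @param mask optional GRanges of callable regions.
#' @return A [WindowTrack-class] with per-window `n_het`, `n_called` and
#'   `het_per_kb`.
#' @export
windowHeterozygosity <- function(x, sample, windows, mask = NULL) {
  .check_samples(x, sample)
  het <- hetCalls(x, sample)[, 1L]
  called <- calledCalls(x, sample)[, 1L]
  ov <- GenomicRanges::findOverlaps(windows, x@sites)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  n_win <- length(windows)
  n_het <- tabulate(q[het[s] %in% TRUE], nbins = n_win)
  n_called <- tabulate(q[called[s]], nbins = n_win)
  n_missing <- tabulate(q[!called[s]], nbins = n_win)
  denom <- BiocGenerics::width(windows)
  if (!is.null(mask)) {
    covered <- GenomicRanges::reduce(mask)
    mv <- GenomicRanges::findOverlaps(windows, covered)
    iw <- BiocGenerics::width(IRanges::pintersect(
      GenomicRanges::granges(windows)[S4Vectors::queryHits(mv)],
      covered[S4Vectors::subjectHits(mv)]))
    denom <- as.numeric(rowsum(c(iw, rep(0L, n_win)),
                               c(S4Vectors::queryHits(mv), seq_len(n_win))))
    denom <- pmax(denom - n_missing, 0)
  }
  track <- GenomicRanges::granges(windows)
  S4Vectors::mcols(track) <- S4Vectors::DataFrame(
    n_het = n_het, n_called = n_called,
    het_per_kb = ifelse(denom > 0, n_het / (denom / 1000), NA_real_))
  new("WindowTrack", sampleId = sample, track = track)
}

#' @describeIn windowHeterozygosity the underlying GRanges of a WindowTrack.
#' @param track a [WindowTrack-class].
#' @export
trackWindows <- function(track) track@track

#' Genome-wide per-site heterozygosity of one sample
#'
#' Total heterozygous genotypes divided by the callable genome length,
#' reported per kb (the scale on which per-site autosomal heterozygosity is
#' conventionally plotted, roughly 0.3-2 het/kb across wild canids).
#'
#' @param x a [VariantPanel-class].
#' @param sample sample id.
#' @param callableLength callable genome length in bp; defaults to the total
#'   layout length.
#' @return Heterozygous sites per kb (numeric scalar).
#' @export
perSiteHeterozygosity <- function(x, sample, callableLength = genomeSize(x)) {
  .check_samples(x, sample)
  if (is.na(callableLength) || callableLength <= 0)
    stop("callableLength must be > 0")
  h <- hetCalls(x, sample)[, 1L]
  sum(h, na.rm = TRUE) / (callableLength / 1000)
}

#' Write a WindowTrack to TSV and BEDGRAPH
#'
#' The TSV has columns chrom, start, end, n_het, n_called, het_per_kb with a
#' commented provenance header; coordinates are 0-based half-open as in BED.
#'
#' @param track a [WindowTrack-class].
#' @param path output TSV path; a `.bedgraph` twin is written alongside when
#'   `bedgraph = TRUE`.
#' @param bedgraph also write a BEDGRAPH of het_per_kb.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeWindowTrack <- function(track, path, bedgraph = FALSE, seed = NULL) {
  gr <- track@track
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   n_het = mc$n_het, n_called = mc$n_called,
                   het_per_kb = mc$het_per_kb)
  .write_tsv(df, path, seed = seed)
  if (bedgraph) {
    bg <- file.path(dirname(path),
                    paste0(tools::file_path_sans_ext(basename(path)),
                           ".bedgraph"))
    writeLines(c(paste0("track type=bedGraph name=het_", track@sampleId),
                 paste(df$chrom, df$start, df$end,
                       formatC(df$het_per_kb, format = "g"), sep = "\t")),
               bg)
  }
  invisible(path)
}

.write_tsv <- function(df, path, seed = NULL) {
  hdr <- paste0("# comparascan ",
                as.character(utils::packageVersion("comparascan")),
                if (!is.null(seed)) paste0(" seed=", seed))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, function(col)
      if (is.numeric(col)) formatC(col, format = "g", digits = 10)
      else as.character(col)), sep = "\t")), con)
  invisible(path)
}
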