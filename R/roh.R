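#' ROH caller parameters
#'
#' @param scanSnpCount sites per scanning window (default 50).
#' @param maxHetInScan max heterozygous genotypes tolerated per scanning
#'   window (default 1).
#' @param maxMissingInScan max missing genotypes per scanning window
#'   (default 5).
#' @param hitThreshold minimum fraction of covering windows that must be
#'   hits for a site to qualify (default 0.05).
#' @param minSnps minimum sites per reported run (default 100).
#' @param minLength minimum run span in bp (default 100 kb).
#' @param maxGap maximum inter-site gap inside a run in bp (default 1 Mb).
#' @return A [ROHParams-class].
#' @export
rohParams <- function(scanSnpCount = 50L, maxHetInScan = 1L,
                      maxMissingInScan = 5L, hitThreshold = 0.05,
                      minSnps = 100L, minLength = 1e5, maxGap = 1e6) {
  new("ROHParams", scanSnpCount = as.integer(scanSnpCount),
      maxHetInScan = as.integer(maxHetInScan),
      maxMissingInScan = as.integer(maxMissingInScan),
      hitThreshold = hitThreshold, minSnps = as.integer(minSnps),
      minLength = minLength, maxGap = maxGap)
}

## Length classes: short [0.1, 1) Mb, medium [1, 10) Mb, long >= 10 Mb.
## Half-open lower bounds: a segment of exactly 1 Mb (10 Mb) is medium (long).
.ROH_CLASSES <- c("short", "medium", "long")

#' Length class of ROH segments
#' @param length_bp numeric vector of segment lengths in bp.
#' @return Factor with levels short/medium/long; NA below 0.1 Mb.
#' @export
rohLengthClass <- function(length_bp) {
  cls <- ifelse(length_bp >= 1e7, "long",
                ifelse(length_bp >= 1e6, "medium",
                       ifelse(length_bp >= 1e5, "short", NA_character_)))
  factor(cls, levels = .ROH_CLASSES)
}

#' Call runs of homozygosity for one sample
#'
#' Scanning-window algorithm in the PLINK `--homozyg` style: a window of
#' `scanSnpCount` consecutive sites is a hit iff it contains at most
#' `maxHetInScan` heterozygous and at most `maxMissingInScan` missing
#' genotypes for the sample. Each site's hit fraction is the proportion of
#' windows covering it that are hits; maximal runs of consecutive sites with
#' hit fraction >= `hitThreshold`, split wherever the inter-site gap exceeds
#' `maxGap`, are reported when they contain at least `minSnps` sites and span
#' at least `minLength` bp. Segment bounds are the first and last site of the
#' run (site-defined, not window-defined).
#'
#' @param x a [VariantPanel-class].
#' @param sample sample id.
#' @param params a [ROHParams-class].
#' @return GRanges of segments with mcols `sample_id`, `n_snps`,
#'   `length_class`. Chromosomes with fewer than `scanSnpCount` sites are
#'   skipped with a warning.
#' @export
callROH <- function(x, sample, params = rohParams()) {
  .check_samples(x, sample)
  het <- hetCalls(x, sample)[, 1L]
  called <- calledCalls(x, sample)[, 1L]
  chrom <- as.character(GenomeInfoDb::seqnames(x@sites))
  pos <- BiocGenerics::start(x@sites)
  segs <- list()
  for (ch in GenomeInfoDb::seqlevels(x@sites)) {
    sel <- chrom == ch
    n <- sum(sel)
    if (n == 0) next
    if (n < params@scanSnpCount) {
      warning("chromosome ", ch, " has ", n, " < ", params@scanSnpCount,
              " sites; skipped")
      next
    }
    p <- pos[sel]
    is_het <- het[sel] %in% TRUE
    is_miss <- !called[sel]
    w <- params@scanSnpCount
    nw <- n - w + 1L
    ch_cum <- c(0L, cumsum(is_het))
    ms_cum <- c(0L, cumsum(is_miss))
    het_in <- ch_cum[(w + 1L):(n + 1L)] - ch_cum[1:nw]
    mis_in <- ms_cum[(w + 1L):(n + 1L)] - ms_cum[1:nw]
    hit <- het_in <= params@maxHetInScan & mis_in <= params@maxMissingInScan
    hit_cum <- c(0L, cumsum(hit))
    j <- seq_len(n)
    lo <- pmax(1L, j - w + 1L)
    hi <- pmin(j, nw)
    frac <- (hit_cum[hi + 1L] - hit_cum[lo]) / (hi - lo + 1L)
    qual <- frac >= params@hitThreshold
    idx <- which(qual)
    if (!length(idx)) next
    ## split runs at non-qualifying sites or gaps above maxGap
    brk <- c(TRUE, diff(idx) > 1L | diff(p[idx]) > params@maxGap)
    run_id <- cumsum(brk)
    for (r in split(idx, run_id)) {
      span <- p[r[length(r)]] - p[r[1]] + 1
      if (length(r) >= params@minSnps && span >= params@minLength) {
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = p[r[1]], end = p[r[length(r)]],
          n_snps = length(r))
      }
    }
  }
  if (!length(segs)) {
    out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(x@sites))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      sample_id = character(0), n_snps = integer(0),
      length_class = factor(character(0), levels = .ROH_CLASSES))
    return(out)
  }
  df <- do.call(rbind, segs)
  out <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                seqinfo = GenomeInfoDb::seqinfo(x@sites))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    sample_id = rep(sample, nrow(df)), n_snps = df$n_snps,
    length_class = rohLengthClass(BiocGenerics::width(out)))
  out
}

#' Classify ROH segments and summarize counts, lengths and genome fractions
#'
#' Segments are assigned to the three canonical length classes - short
#' (0.1 Mb to 1 Mb), medium (1 Mb to 10 Mb) and long (>= 10 Mb) - and
#' summarized as counts, summed lengths and fractions of the genome, plus
#' F_ROH (total ROH length / genome length), the genomic inbreeding
#' coefficient. Segments below 0.1 Mb are excluded and counted in a discard
#' tally.
#'
#' @param segments GRanges of ROH segments (e.g. from [callROH()]).
#' @param layout genome layout (`Seqinfo`).
#' @return A list with elements `per_class` (data.frame class, n_segments,
#'   summed_bp, fraction), `froh`, and `n_discarded`.
#' @export
classifyAndSummarize <- function(segments, layout) {
  wid <- BiocGenerics::width(segments)
  cls <- rohLengthClass(wid)
  keep <- !is.na(cls)
  gsize <- genomeSize(layout)
  per <- data.frame(
    class = .ROH_CLASSES,
    n_segments = as.integer(table(cls[keep])[.ROH_CLASSES]),
    summed_bp = as.numeric(tapply(wid[keep], cls[keep], sum,
                                  default = 0)[.ROH_CLASSES]))
  per$n_segments[is.na(per$n_segments)] <- 0L
  per$summed_bp[is.na(per$summed_bp)] <- 0
  per$fraction <- per$summed_bp / gsize
  list(per_class = per, froh = sum(per$summed_bp) / gsize,
       n_discarded = sum(!keep))
}

#' Write ROH segments as BED3+ (chrom, start, end, n_snps, class, sample)
#'
#' Coordinates are 0-based half-open.
#'
#' @param segments GRanges from [callROH()].
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeROHBed <- function(segments, path, seed = NULL) {
  mc <- S4Vectors::mcols(segments)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(segments)),
                   start = BiocGenerics::start(segments) - 1L,
                   end = BiocGenerics::end(segments),
                   n_snps = mc$n_snps,
                   class = as.character(mc$length_class),
                   sample_id = mc$sample_id)
  .write_tsv(df, path, seed = seed)
}
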