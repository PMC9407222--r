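#' Read transcript models from GFF3 or BED12
#'
#' GFF3 features of type `mRNA` or `transcript` are used; the gene id is
#' resolved from the feature's own `gene_id` attribute or from its `Parent`
#' (with any `gene:` prefix stripped). For BED12, the gene id is encoded in
#' the name column as `gene<sep>transcript` (see `nameSep`); a name without
#' the separator is used as both gene and transcript id.
#'
#' @param path a GFF3 (`.gff`, `.gff3`, optionally gzipped) or BED12 file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param nameSep separator between gene and transcript id in BED names.
#' @return A `GRanges` with mcols `gene_id` and `transcript_id`, strand
#'   preserved; one range per transcript.
#' @export
readTranscripts <- function(path, format = c("auto", "gff3", "bed"),
                            nameSep = "|") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", tolower(basename(path))))
      "bed" else "gff3"
  lines <- readLines(path)
  if (!length(grep("^[^#]", lines, value = TRUE))) {
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      gene_id = character(0), transcript_id = character(0))
    return(empty)
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm) || anyNA(nm))
      stop("BED transcript without a name (needed to resolve gene_id)")
    split_nm <- strsplit(nm, nameSep, fixed = TRUE)
    gene <- vapply(split_nm, `[`, character(1), 1L)
    tx <- vapply(split_nm, function(p) p[min(2L, length(p))], character(1))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = gene,
                                                 transcript_id = tx)
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_tx <- as.character(mc$type) %in% c("mRNA", "transcript")
  tx <- gr[is_tx]
  mtx <- S4Vectors::mcols(tx)
  gene <- if (!is.null(mtx$gene_id)) as.character(mtx$gene_id)
          else rep(NA_character_, length(tx))
  if (anyNA(gene) && !is.null(mtx$Parent)) {
    parent <- vapply(as.list(mtx$Parent), function(p)
      if (length(p)) sub("^gene:", "", p[1]) else NA_character_, character(1))
    gene <- ifelse(is.na(gene), parent, gene)
  }
  if (anyNA(gene)) {
    bad <- which(is.na(gene))[1]
    stop("transcript without resolvable gene_id: ",
         as.character(GenomeInfoDb::seqnames(tx))[bad], ":",
         BiocGenerics::start(tx)[bad], "-", BiocGenerics::end(tx)[bad],
         " id=", if (!is.null(mtx$ID)) mtx$ID[bad] else "?")
  }
  txid <- if (!is.null(mtx$ID)) sub("^transcript:", "", as.character(mtx$ID))
          else paste0(gene, ".t", seq_along(tx))
  out <- GenomicRanges::granges(tx)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(gene_id = gene,
                                                transcript_id = txid)
  out
}

#' Keep the longest isoform of each gene
#'
#' When a gene has several transcripts, retains the longest one (ties broken
#' by transcript id for determinism), mirroring standard practice of testing
#' one isoform per gene.
#'
#' @param transcripts GRanges from [readTranscripts()].
#' @return A GRanges with one transcript per gene, in input gene order.
#' @export
longestIsoforms <- function(transcripts) {
  if (!length(transcripts)) return(transcripts)
  mc <- S4Vectors::mcols(transcripts)
  o <- order(mc$gene_id, -BiocGenerics::width(transcripts),
             mc$transcript_id)
  sorted <- transcripts[o]
  keep <- !duplicated(S4Vectors::mcols(sorted)$gene_id)
  sel <- sorted[keep]
  sel[order(match(S4Vectors::mcols(sel)$gene_id, unique(mc$gene_id)))]
}

#' Write transcript models to GFF3
#'
#' Emits one `gene` and one `mRNA` feature per transcript, linked by
#' `ID`/`Parent`; output is byte-deterministic for a given input.
#'
#' @param transcripts GRanges with mcols `gene_id`, `transcript_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTranscriptsGFF3 <- function(transcripts, path) {
  mc <- S4Vectors::mcols(transcripts)
  chrom <- as.character(GenomeInfoDb::seqnames(transcripts))
  st <- BiocGenerics::start(transcripts)
  en <- BiocGenerics::end(transcripts)
  sd <- as.character(BiocGenerics::strand(transcripts))
  sd[sd == "*"] <- "."
  first_tx <- !duplicated(mc$gene_id)
  gene_lines <- paste(chrom[first_tx], "comparascan", "gene", st[first_tx],
                      en[first_tx], ".", sd[first_tx], ".",
                      paste0("ID=gene:", mc$gene_id[first_tx]), sep = "\t")
  tx_lines <- paste(chrom, "comparascan", "mRNA", st, en, ".", sd, ".",
                    paste0("ID=transcript:", mc$transcript_id,
                           ";Parent=gene:", mc$gene_id), sep = "\t")
  ## interleave: each gene line before its transcripts, preserving input order
  ord <- order(match(mc$gene_id, mc$gene_id[first_tx]))
  out <- character(0)
  if (length(transcripts)) {
    grouped <- split(tx_lines[ord], match(mc$gene_id, mc$gene_id[first_tx])[ord])
    out <- unlist(lapply(seq_along(gene_lines), function(i)
      c(gene_lines[i], grouped[[i]])), use.names = FALSE)
  }
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}
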