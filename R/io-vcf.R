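## VCF input goes through vcfR; output is formatted directly (the on-disk
## representation of a VariantPanel is a plain VCF 4.2 with GT genotypes and
## the annotation INFO keys below).

.info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
         character(1))
}

.info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

#' Read a multi-sample VCF into a VariantPanel
#'
#' Parses diploid genotypes for the panel samples plus optional ancestral
#' allele and annotation INFO keys. Multiallelic sites are kept unsplit.
#' Sites must be sorted by chromosome (in layout order) and position.
#'
#' @param path a VCF 4.x file (plain or gzip/bgzip).
#' @param panel a [SpeciesPanel-class]; every panel sample must appear in the
#'   VCF header.
#' @param layout genome layout (`Seqinfo`); when `NULL` it is taken from the
#'   VCF `##contig` header lines.
#' @param aaKey INFO key holding the ancestral allele (default `AA`).
#' @param impactKey INFO key holding the impact category (default `IMPACT`).
#' @param delKey INFO key holding the deleterious flag (default `DEL`;
#'   `DEL=1`/`DEL=0` or a bare flag are accepted).
#' @param geneKey INFO key holding the gene id (default `GENE`).
#' @return A [VariantPanel-class].
#' @export
readVariantPanel <- function(path, panel, layout = NULL, aaKey = "AA",
                             impactKey = "IMPACT", delKey = "DEL",
                             geneKey = "GENE") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, convertNA = FALSE)
  hdr_samples <- colnames(vcf@gt)[-1L]
  missing_s <- setdiff(sampleIds(panel), hdr_samples)
  if (length(missing_s))
    stop("panel sample(s) not in VCF header: ",
         paste(missing_s, collapse = ", "))
  if (is.null(layout)) {
    contig <- grep("^##contig=", vcf@meta, value = TRUE)
    if (!length(contig))
      stop("no layout given and no ##contig header lines in VCF")
    ids <- sub(".*<ID=([^,>]+).*", "\\1", contig)
    lens <- as.integer(sub(".*[,<]length=([0-9]+).*", "\\1", contig))
    layout <- genomeLayout(ids, lens)
  }
  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  chr_idx <- match(chrom, GenomeInfoDb::seqnames(layout))
  if (anyNA(chr_idx)) {
    bad <- which(is.na(chr_idx))[1]
    stop("chromosome not in layout at record ", chrom[bad], ":", pos[bad])
  }
  if (length(pos) > 1L) {
    key <- chr_idx * (max(pos) + 1) + pos
    off <- which(diff(key) <= 0)
    if (length(off))
      stop("VCF not sorted; first offending record: ",
           chrom[off[1] + 1L], ":", pos[off[1] + 1L])
  }
  info <- fix[, "INFO"]
  if (all(is.na(info))) info <- rep(".", length(pos))
  alt_str <- fix[, "ALT"]
  alt <- IRanges::CharacterList(strsplit(ifelse(is.na(alt_str) |
                                                  alt_str == ".",
                                                "", alt_str), ","))
  del_val <- .info_value(info, delKey)
  del <- ifelse(!is.na(del_val), del_val %in% c("1", "TRUE", "T"),
                ifelse(.info_flag(info, delKey), TRUE, NA))
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                  seqinfo = layout)
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    ref = fix[, "REF"], alt = alt,
    ancestral = .info_value(info, aaKey),
    impact = .info_value(info, impactKey),
    deleterious = as.logical(del),
    gene_id = .info_value(info, geneKey))

  gt <- vcf@gt[, sampleIds(panel), drop = FALSE]
  g <- sub(":.*", "", gt)
  a1 <- suppressWarnings(as.integer(sub("[/|].*", "", g)))
  a2 <- suppressWarnings(as.integer(sub(".*[/|]", "", g)))
  dim(a1) <- dim(a2) <- dim(g)
  colnames(a1) <- colnames(a2) <- colnames(g)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  VariantPanel(sites, a1, a2, panel)
}

#' Write a VariantPanel to a VCF 4.2 file
#'
#' Emits GT genotypes plus `AA`, `IMPACT`, `DEL` and `GENE` INFO keys for the
#' sites where the corresponding annotation is present. Re-reading the file
#' with [readVariantPanel()] reproduces genotypes and annotations exactly.
#'
#' @param x a [VariantPanel-class].
#' @param path output path; a `.gz` suffix writes gzip-compressed text.
#' @param seed optional integer recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
writeVariantPanel <- function(x, path, seed = NULL) {
  si <- GenomeInfoDb::seqinfo(x@sites)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=comparascan_",
                   as.character(utils::packageVersion("comparascan")),
                   if (!is.null(seed)) paste0(" seed=", seed)),
            paste0("##contig=<ID=", GenomeInfoDb::seqnames(si), ",length=",
                   GenomeInfoDb::seqlengths(si), ">"),
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact category\">",
            "##INFO=<ID=DEL,Number=1,Type=Integer,Description=\"Deleterious flag\">",
            "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sampleIds(x)), collapse = "\t")
  mc <- S4Vectors::mcols(x@sites)
  n <- length(x@sites)
  alt <- vapply(mc$alt, function(a)
    if (length(a)) paste(a, collapse = ",") else ".", character(1))
  parts <- cbind(
    ifelse(is.na(mc$ancestral), NA, paste0("AA=", mc$ancestral)),
    ifelse(is.na(mc$impact), NA, paste0("IMPACT=", mc$impact)),
    ifelse(is.na(mc$deleterious), NA,
           paste0("DEL=", as.integer(mc$deleterious))),
    ifelse(is.na(mc$gene_id), NA, paste0("GENE=", mc$gene_id)))
  info <- apply(parts, 1L, function(p) {
    p <- p[!is.na(p)]
    if (length(p)) paste(p, collapse = ";") else "."
  })
  if (!n) info <- character(0)
  gt <- matrix(paste(x@gt1, x@gt2, sep = "/"), nrow = n,
               dimnames = dimnames(x@gt1))
  gt[is.na(x@gt1)] <- "./."
  body <- paste(as.character(GenomeInfoDb::seqnames(x@sites)),
                BiocGenerics::start(x@sites), ".", mc$ref, alt, ".", ".",
                info, "GT", sep = "\t")
  if (n && ncol(gt))
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(meta, header, if (n) body), con)
  invisible(path)
}
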