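#' Construct a VariantPanel from sites and genotype matrices
#'
#' @param sites GRanges of width-1 variant positions carrying at least mcols
#'   `ref` (character) and `alt` (CharacterList); optional `ancestral`,
#'   `impact`, `deleterious`, `gene_id` are filled with NA when absent. The
#'   seqinfo of `sites` is the genome layout.
#' @param gt1,gt2 integer allele-index matrices (sites x samples), columns
#'   named and ordered as the panel sample ids; `NA` encodes missing.
#' @param panel a [SpeciesPanel-class].
#' @return A [VariantPanel-class], sites sorted by (chromosome order,
#'   position).
#' @export
VariantPanel <- function(sites, gt1, gt2, panel) {
  mc <- S4Vectors::mcols(sites)
  if (is.null(mc$alt) || !is(mc$alt, "CharacterList"))
    mc$alt <- IRanges::CharacterList(as.list(mc$alt))
  n <- length(sites)
  for (col in c("ancestral", "impact", "gene_id"))
    if (is.null(mc[[col]])) mc[[col]] <- rep(NA_character_, n)
  if (is.null(mc$deleterious)) mc$deleterious <- rep(NA, n)
  mc$deleterious <- as.logical(mc$deleterious)
  S4Vectors::mcols(sites) <- mc
  o <- order(as.integer(GenomeInfoDb::seqnames(sites)),
             BiocGenerics::start(sites))
  storage.mode(gt1) <- "integer"
  storage.mode(gt2) <- "integer"
  new("VariantPanel", sites = sites[o],
      gt1 = gt1[o, , drop = FALSE], gt2 = gt2[o, , drop = FALSE],
      panel = panel)
}

#' @describeIn VariantPanel the sorted GRanges of variant sites with allele
#'   and annotation metadata columns.
#' @param x a VariantPanel.
#' @export
variantSites <- function(x) x@sites

#' @describeIn VariantPanel the species panel.
#' @export
samplePanel <- function(x) x@panel

#' @describeIn VariantPanel number of variant sites.
#' @export
nSites <- function(x) length(x@sites)

#' @describeIn VariantPanel list of the two allele-index matrices.
#' @export
genotypeMatrices <- function(x) list(gt1 = x@gt1, gt2 = x@gt2)

#' Heterozygous-genotype indicator matrix
#'
#' @param x a [VariantPanel-class].
#' @param samples sample ids (default all).
#' @return Logical sites x samples matrix: TRUE where the two allele indices
#'   differ, FALSE where homozygous, NA where missing.
#' @export
hetCalls <- function(x, samples = sampleIds(x)) {
  .check_samples(x, samples)
  x@gt1[, samples, drop = FALSE] != x@gt2[, samples, drop = FALSE]
}

#' Called-genotype indicator matrix
#'
#' @inheritParams hetCalls
#' @return Logical sites x samples matrix, TRUE where the genotype is called.
#' @export
calledCalls <- function(x, samples = sampleIds(x)) {
  .check_samples(x, samples)
  !is.na(x@gt1[, samples, drop = FALSE])
}

.check_samples <- function(x, samples) {
  bad <- setdiff(samples, sampleIds(x))
  if (length(bad))
    stop("unknown sample(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Subset a VariantPanel to a set of chromosomes
#'
#' Used e.g. to exclude the X chromosome from autosomal summaries.
#'
#' @param x a [VariantPanel-class].
#' @param exclude chromosome names to drop.
#' @return A [VariantPanel-class] restricted to the remaining chromosomes;
#'   the seqinfo keeps only the retained chromosomes.
#' @export
dropChromosomes <- function(x, exclude) {
  if (!length(exclude)) return(x)
  keep_chr <- setdiff(GenomeInfoDb::seqlevels(x@sites), exclude)
  keep <- as.character(GenomeInfoDb::seqnames(x@sites)) %in% keep_chr
  sites <- x@sites[keep]
  GenomeInfoDb::seqlevels(sites, pruning.mode = "coarse") <- keep_chr
  new("VariantPanel", sites = sites,
      gt1 = x@gt1[keep, , drop = FALSE], gt2 = x@gt2[keep, , drop = FALSE],
      panel = x@panel)
}

#' Allele strings carried by a genotype matrix column
#'
#' Internal helper: allele index matrix -> is the allele at each site equal
#' to the site's ancestral allele.
#' @noRd
.ancestral_index <- function(x) {
  mc <- S4Vectors::mcols(x@sites)
  anc <- mc$ancestral
  idx <- rep(NA_integer_, length(anc))
  is_ref <- !is.na(anc) & anc == mc$ref
  idx[is_ref] <- 0L
  todo <- which(!is.na(anc) & !is_ref)
  if (length(todo)) {
    alt <- mc$alt[todo]
    idx[todo] <- vapply(seq_along(todo), function(i) {
      m <- match(anc[todo[i]], alt[[i]])
      if (is.na(m)) NA_integer_ else m
    }, integer(1))
  }
  idx
}

setMethod("show", "VariantPanel", function(object) {
  si <- GenomeInfoDb::seqinfo(object@sites)
  cat("VariantPanel:", length(object@sites), "sites,",
      ncol(object@gt1), "samples,",
      length(GenomeInfoDb::seqnames(si)), "chromosomes (",
      format(genomeSize(si), big.mark = ","), "bp )\n")
  mc <- S4Vectors::mcols(object@sites)
  cat("  ancestral alleles:", sum(!is.na(mc$ancestral)),
      "| impact-annotated:", sum(!is.na(mc$impact)),
      "| deleterious-flagged:", sum(!is.na(mc$deleterious) & mc$deleterious),
      "\n")
  show(object@panel)
})
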