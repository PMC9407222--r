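#' Lineage-unique high-impact variants per focal species
#'
#' Filters the panel to sites annotated with impact category `HIGH` whose
#' (derived, when polarized) allele is private to the focal species, and
#' groups them by gene. Both tallies are reported: the number of distinct
#' genes carrying at least one such variant and the number of variants.
#'
#' @param x a [VariantPanel-class]; at least one site must carry an impact
#'   annotation.
#' @param focal focal species id.
#' @param panel a [SpeciesPanel-class] (defaults to the panel of `x`).
#' @return A list: `focal`, `genes` (sorted unique gene ids), `variants`
#'   (data.frame chrom, pos, ref, alt, gene_id, impact), `n_genes`,
#'   `n_variants`.
#' @export
uniqueHighImpact <- function(x, focal, panel = samplePanel(x)) {
  mc <- S4Vectors::mcols(x@sites)
  if (all(is.na(mc$impact)))
    stop("no impact annotations on any site; supply a VCF with an impact ",
         "INFO key (see readVariantPanel argument impactKey)")
  sel <- !is.na(mc$impact) & mc$impact == "HIGH" & isPrivate(x, focal, panel)
  sites <- x@sites[sel]
  smc <- S4Vectors::mcols(sites)
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    pos = BiocGenerics::start(sites),
    ref = smc$ref,
    alt = vapply(smc$alt, paste, character(1), collapse = ","),
    gene_id = smc$gene_id,
    impact = smc$impact)
  genes <- sort(unique(variants$gene_id[!is.na(variants$gene_id)]))
  list(focal = focal, genes = genes, variants = variants,
       n_genes = length(genes), n_variants = nrow(variants))
}

#' Damaging-genotype load of one sample
#'
#' Counts, over sites flagged deleterious and polarized by an ancestral
#' allele, the genotypes homozygous for an allele differing from the
#' ancestral allele (`n_damaging_hom_derived`) and the heterozygous genotypes
#' carrying at least one derived allele (`n_damaging_het`). The reference
#' allele is never assumed ancestral: a homozygous-reference genotype counts
#' when the ancestral allele is an alternate allele. Deleterious sites
#' without an ancestral allele are excluded and tallied.
#'
#' @param x a [VariantPanel-class].
#' @param sample sample id.
#' @return data.frame with one row: sample_id, n_damaging_hom_derived,
#'   n_damaging_het, denominator (deleterious polarized sites with a called
#'   genotype for the sample), n_excluded_no_ancestral.
#' @export
damagingLoad <- function(x, sample) {
  .check_samples(x, sample)
  mc <- S4Vectors::mcols(x@sites)
  del <- !is.na(mc$deleterious) & mc$deleterious
  no_anc <- del & is.na(mc$ancestral)
  use <- del & !is.na(mc$ancestral)
  g1 <- x@gt1[, sample]; g2 <- x@gt2[, sample]
  anc_idx <- .ancestral_index(x)
  ## an allele index is derived iff it differs from the ancestral index; when
  ## the ancestral allele matches none of the site's alleles every called
  ## allele is derived
  derived1 <- is.na(anc_idx) | g1 != anc_idx
  derived2 <- is.na(anc_idx) | g2 != anc_idx
  called <- !is.na(g1)
  hom_derived <- use & called & g1 == g2 & derived1
  het_derived <- use & called & g1 != g2 & (derived1 | derived2)
  data.frame(sample_id = sample,
             n_damaging_hom_derived = sum(hom_derived, na.rm = TRUE),
             n_damaging_het = sum(het_derived, na.rm = TRUE),
             denominator = sum(use & called),
             n_excluded_no_ancestral = sum(no_anc))
}

#' Damaging-genotype load for every sample of the panel
#'
#' @param x a [VariantPanel-class].
#' @return data.frame with one row per sample, as in [damagingLoad()].
#' @export
damagingLoadAll <- function(x) {
  do.call(rbind, lapply(sampleIds(x), function(s) damagingLoad(x, s)))
}
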