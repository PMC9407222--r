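## Central S4 containers. The genome layout is a GenomeInfoDb::Seqinfo;
## windows, transcripts and ROH segments are plain GRanges. Only objects with
## real invariants get their own class.

#' SpeciesPanel: sample-to-species map with focal/background partition
#'
#' Maps each sample of a multi-sample VCF to a species and declares which
#' species are the focal lineages of downstream scans (private alleles,
#' high-impact filtering) versus the background ("remaining") species.
#'
#' @slot samples data.frame with columns `sample_id`, `species_id`.
#' @slot focal character vector of focal species ids.
#' @slot background character vector of background species ids.
#' @export
setClass("SpeciesPanel",
  slots = c(samples = "data.frame", focal = "character",
            background = "character"))

setValidity("SpeciesPanel", function(object) {
  s <- object@samples
  msg <- character()
  if (!all(c("sample_id", "species_id") %in% names(s)))
    msg <- c(msg, "samples must have columns sample_id, species_id")
  else {
    if (anyDuplicated(s$sample_id))
      msg <- c(msg, "sample_ids must be unique")
    declared <- c(object@focal, object@background)
    absent <- setdiff(declared, s$species_id)
    if (length(absent))
      msg <- c(msg, paste0("species without samples: ",
                           paste(absent, collapse = ", ")))
  }
  if (length(intersect(object@focal, object@background)))
    msg <- c(msg, "focal and background species sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' VariantPanel: multi-sample diploid genotypes over sorted variant sites
#'
#' Sites are a sorted `GRanges` (width-1 positions) whose metadata columns
#' carry `ref`, `alt` (a `CharacterList`, multiallelic sites unsplit),
#' optional `ancestral` allele, `impact` category (HIGH/MODERATE/LOW/
#' MODIFIER), `deleterious` flag and `gene_id`. Genotypes are two integer
#' allele-index matrices (sites x samples); `NA` in both encodes a missing
#' genotype (`./.`). A genotype is heterozygous iff its two allele indices
#' differ, regardless of which alleles are involved.
#'
#' @slot sites GRanges of variant positions with allele/annotation mcols.
#' @slot gt1,gt2 integer matrices of allele indices (0 = REF).
#' @slot panel a [SpeciesPanel-class].
#' @export
setClass("VariantPanel",
  slots = c(sites = "GRanges", gt1 = "matrix", gt2 = "matrix",
            panel = "SpeciesPanel"))

setValidity("VariantPanel", function(object) {
  msg <- character()
  n <- length(object@sites)
  mc <- S4Vectors::mcols(object@sites)
  need <- c("ref", "alt", "ancestral", "impact", "deleterious", "gene_id")
  if (!all(need %in% names(mc)))
    msg <- c(msg, paste0("sites must carry mcols: ",
                         paste(need, collapse = ", ")))
  if (nrow(object@gt1) != n || nrow(object@gt2) != n)
    msg <- c(msg, "genotype matrices must have one row per site")
  ids <- object@panel@samples$sample_id
  if (!identical(colnames(object@gt1), ids) ||
      !identical(colnames(object@gt2), ids))
    msg <- c(msg, "genotype matrix columns must match panel sample_ids")
  if (n > 1) {
    o <- order(as.integer(GenomeInfoDb::seqnames(object@sites)),
               BiocGenerics::start(object@sites))
    if (!identical(o, seq_len(n)))
      msg <- c(msg, "sites must be sorted by (chromosome order, position)")
  }
  if (n > 0) {
    sl <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(object@sites))
    ends <- BiocGenerics::end(object@sites)
    lim <- sl[as.character(GenomeInfoDb::seqnames(object@sites))]
    if (any(!is.na(lim) & ends > lim))
      msg <- c(msg, "site position exceeds chromosome length")
    nall <- 1L + lengths(mc$alt)
    mx <- pmax(object@gt1, object@gt2)
    bad <- !is.na(mx) & mx > (nall - 1L)
    if (any(bad))
      msg <- c(msg, "genotype allele index outside ref/alt range")
  }
  if (length(msg)) msg else TRUE
})

#' WindowTrack: per-window heterozygosity statistics for one sample
#'
#' @slot sampleId the sample the track belongs to.
#' @slot track GRanges of windows with mcols `n_het`, `n_called`,
#'   `het_per_kb` (heterozygous genotypes per kb of callable window length).
#' @export
setClass("WindowTrack",
  slots = c(sampleId = "character", track = "GRanges"))

setValidity("WindowTrack", function(object) {
  mc <- S4Vectors::mcols(object@track)
  msg <- character()
  if (!all(c("n_het", "n_called", "het_per_kb") %in% names(mc)))
    msg <- c(msg, "track must carry mcols n_het, n_called, het_per_kb")
  else if (any(mc$n_het > mc$n_called))
    msg <- c(msg, "n_het must not exceed n_called")
  if (length(msg)) msg else TRUE
})

#' ROHParams: parameters of the scanning-window ROH caller
#'
#' Defaults mirror common PLINK `--homozyg` practice: windows of 50
#' consecutive sites, at most 1 heterozygous and 5 missing genotypes per
#' scanning window, a site qualifies when at least 5% of the windows covering
#' it are hits, and reported runs must contain at least 100 sites, span at
#' least 100 kb and have no inter-site gap above 1 Mb.
#'
#' @slot scanSnpCount sites per scanning window.
#' @slot maxHetInScan,maxMissingInScan per-window tolerance counts.
#' @slot hitThreshold minimum hit fraction for a site to qualify.
#' @slot minSnps,minLength,maxGap run-level filters (counts, bp, bp).
#' @export
setClass("ROHParams",
  slots = c(scanSnpCount = "integer", maxHetInScan = "integer",
            maxMissingInScan = "integer", hitThreshold = "numeric",
            minSnps = "integer", minLength = "numeric", maxGap = "numeric"))

setValidity("ROHParams", function(object) {
  msg <- character()
  if (object@scanSnpCount < 1L) msg <- c(msg, "scanSnpCount must be >= 1")
  if (object@maxHetInScan < 0L || object@maxMissingInScan < 0L)
    msg <- c(msg, "per-window tolerances must be nonnegative")
  if (object@hitThreshold <= 0 || object@hitThreshold > 1)
    msg <- c(msg, "hitThreshold must be in (0, 1]")
  if (object@minSnps < 0L) msg <- c(msg, "minSnps must be nonnegative")
  if (object@minLength < 1) msg <- c(msg, "minLength must be >= 1")
  if (object@maxGap < 0) msg <- c(msg, "maxGap must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the multi-species genotype simulator
#'
#' @slot seed integer RNG seed; identical seed + config gives byte-identical
#'   output files.
#' @slot layout Seqinfo giving chromosome names and lengths.
#' @slot species data.frame with columns `species_id`, `n_samples`,
#'   `het_rate` (expected heterozygous sites per bp per sample).
#' @slot rohPlan data.frame of autozygous tracts to implant: columns
#'   `sample_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @slot focal character vector of focal species receiving injected private
#'   alleles.
#' @slot privateRate expected private alleles per bp per focal species.
#' @slot targetGenes gene ids whose flanking windows receive
#'   `enrichmentFactor` times the background private-allele rate.
#' @slot enrichmentFactor multiplier >= 1 on the private rate inside target
#'   flanks.
#' @slot targetPrivateRate optional absolute private rate (per bp) inside
#'   target flanks, overriding the multiplicative rule; permits the
#'   degenerate design with zero background and all privates in flanks.
#' @slot damagingFraction probability an injected derived allele is flagged
#'   deleterious.
#' @slot homDamagingBias named per-sample multipliers on the probability
#'   (base 0.5) that a deleterious derived allele is carried homozygous.
#' @slot impactProbs named probabilities over HIGH/MODERATE/LOW/MODIFIER for
#'   injected private alleles.
#' @slot flank flank width in bp used to define target-gene windows.
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", layout = "Seqinfo", species = "data.frame",
            rohPlan = "data.frame", focal = "character",
            privateRate = "numeric", targetGenes = "character",
            enrichmentFactor = "numeric", targetPrivateRate = "numeric",
            damagingFraction = "numeric",
            homDamagingBias = "numeric", impactProbs = "numeric",
            flank = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  sp <- object@species
  if (!all(c("species_id", "n_samples", "het_rate") %in% names(sp)))
    msg <- c(msg, "species must have columns species_id, n_samples, het_rate")
  else {
    if (any(sp$het_rate < 0)) msg <- c(msg, "het_rate must be nonnegative")
    if (any(sp$n_samples < 1)) msg <- c(msg, "n_samples must be >= 1")
    if (anyDuplicated(sp$species_id)) msg <- c(msg, "duplicate species_id")
  }
  if (object@privateRate < 0) msg <- c(msg, "privateRate must be nonnegative")
  if (object@enrichmentFactor < 1)
    msg <- c(msg, "enrichmentFactor must be >= 1")
  if (!is.na(object@targetPrivateRate) &&
      object@targetPrivateRate < object@privateRate)
    msg <- c(msg, "targetPrivateRate must be >= privateRate")
  if (object@damagingFraction < 0 || object@damagingFraction > 1)
    msg <- c(msg, "damagingFraction must be in [0, 1]")
  if (length(object@focal) && !all(object@focal %in% sp$species_id))
    msg <- c(msg, "focal species absent from species table")
  if (abs(sum(object@impactProbs) - 1) > 1e-8)
    msg <- c(msg, "impactProbs must sum to 1")
  if (object@flank < 0L) msg <- c(msg, "flank must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SimTruth: realized ground truth of a simulated panel
#'
#' All counts are recomputed from the genotype matrix actually emitted, never
#' assumed from the configuration.
#'
#' @slot implantedROH GRanges of implanted autozygous tracts with mcol
#'   `sample_id`.
#' @slot enrichedGeneIds gene ids whose flanks received enriched private
#'   rates.
#' @slot privateCounts named per-focal-species realized private-site counts.
#' @slot damagingHomCounts named per-sample realized counts of homozygous
#'   derived deleterious genotypes.
#' @slot nSites number of variant sites emitted.
#' @export
setClass("SimTruth",
  slots = c(implantedROH = "GRanges", enrichedGeneIds = "character",
            privateCounts = "numeric", damagingHomCounts = "numeric",
            nSites = "integer"))
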