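## Reference verification scenarios. These fix the study conditions under
## which the pipeline's recovery properties are demonstrated; the same
## constructors drive the test suite and the acceptance script. Problem sizes
## are chosen to give each check real statistical resolution at desk scale
## (rationale in the methods vignette).

#' Reference simulation scenarios for pipeline verification
#'
#' Each constructor returns the fixed configuration of one verification
#' scenario (only the seed varies):
#'
#' * `simConfigHetRecovery`: three species spanning the empirical range of
#'   wild-canid heterozygosity (0.3, 1.0 and 2.0 het/kb) on a 10-Mb
#'   chromosome, two samples each - used to check that per-site estimates
#'   recover the configured rates within Poisson error and preserve ranking.
#' * `simConfigRohRecovery`: ten "inbred" samples each carrying implanted
#'   autozygous tracts of 0.3, 3 and 30 Mb (staggered across samples) and ten
#'   outbred samples, het rate 1 het/kb, on a 40 + 8 + 4 Mb genome - used to
#'   score tract recovery (Jaccard, length class) and long-ROH false
#'   positives.
#' * `simConfigScanNull`: a null private-allele scan - 2,000 genes, uniform
#'   private rate 0.05/bp, no enrichment. The high rate puts roughly 100
#'   private alleles in each 2-kb flank pair so the discrete binomial test is
#'   effectively continuous and the P-value uniformity check is meaningful.
#' * `simConfigScanPower`: 2,000 genes, background private rate 0.001/bp
#'   (about 2 per flank pair), 10-fold enrichment at 20 target genes - used
#'   to score recall and false positives against a precomputed
#'   model-level oracle.
#' * `simConfigLoadBias`: one focal species of four samples on 5 Mb with
#'   private rate 1e-4/bp and damaging fraction 0.3; sample `focal_1` has
#'   homozygous-damaging bias 2 - used to check that the biased sample ranks
#'   first in damaging-homozygote load.
#'
#' @param seed integer seed.
#' @return For the transcript-based scenarios, a list with elements `config`
#'   (a [SimulationConfig-class]), `transcripts` and (where relevant)
#'   `targets`; otherwise the [SimulationConfig-class] itself.
#' @name studyConfigs
NULL

#' @rdname studyConfigs
#' @export
simConfigHetRecovery <- function(seed) {
  simulationConfig(
    seed = seed,
    layout = genomeLayout("chr1", 10000000L),
    species = data.frame(
      species_id = c("low_het", "mid_het", "high_het"),
      n_samples = 2L,
      het_rate = c(3e-4, 1e-3, 2e-3)))
}

#' @rdname studyConfigs
#' @export
simConfigRohRecovery <- function(seed) {
  layout <- genomeLayout(c("chr1", "chr2", "chr3"),
                         c(40000000L, 8000000L, 4000000L))
  inbred <- paste0("inbred_", 1:10)
  ## one tract per length class per inbred sample, staggered starts
  plan <- do.call(rbind, lapply(seq_along(inbred), function(i) {
    data.frame(
      sample_id = inbred[i],
      chrom = c("chr1", "chr2", "chr3"),
      start = c(1L + (i - 1L) * 1000000L,
                500001L + (i - 1L) * 400000L,
                200001L + (i - 1L) * 300000L),
      end = c(30000000L + (i - 1L) * 1000000L,
              3500000L + (i - 1L) * 400000L,
              500000L + (i - 1L) * 300000L))
  }))
  simulationConfig(
    seed = seed, layout = layout,
    species = data.frame(species_id = c("inbred", "outbred"),
                         n_samples = 10L, het_rate = 1e-3),
    rohPlan = plan)
}

.scan_layout <- function() genomeLayout(c("chr1", "chr2"),
                                        c(5000000L, 5000000L))

#' @rdname studyConfigs
#' @export
simConfigScanNull <- function(seed) {
  layout <- .scan_layout()
  tx <- simulateTranscriptome(layout, 2000L, seed = seed)
  cfg <- simulationConfig(
    seed = seed, layout = layout,
    species = data.frame(species_id = c("focal", "bg1", "bg2"),
                         n_samples = 2L, het_rate = 1e-4),
    focal = "focal", privateRate = 0.05, enrichmentFactor = 1)
  list(config = cfg, transcripts = tx)
}

#' @rdname studyConfigs
#' @export
simConfigScanPower <- function(seed) {
  layout <- .scan_layout()
  tx <- simulateTranscriptome(layout, 2000L, seed = seed)
  targets <- S4Vectors::mcols(tx)$gene_id[seq(50L, 1950L, by = 100L)]
  cfg <- simulationConfig(
    seed = seed, layout = layout,
    species = data.frame(species_id = c("focal", "bg1", "bg2"),
                         n_samples = 2L, het_rate = 1e-4),
    focal = "focal", privateRate = 0.001, targetGenes = targets,
    enrichmentFactor = 10)
  list(config = cfg, transcripts = tx, targets = targets)
}

#' @rdname studyConfigs
#' @export
simConfigLoadBias <- function(seed) {
  simulationConfig(
    seed = seed,
    layout = genomeLayout("chr1", 5000000L),
    species = data.frame(species_id = c("focal", "bg1", "bg2"),
                         n_samples = c(4L, 2L, 2L),
                         het_rate = c(5e-4, 5e-4, 5e-4)),
    focal = "focal", privateRate = 1e-4, damagingFraction = 0.3,
    homDamagingBias = c(focal_1 = 2))
}
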