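#' Write a small self-contained demonstration data set and run config
#'
#' Simulates a three-species panel on a 3-Mb toy genome - one species with an
#' implanted 1.2-Mb autozygous tract, one focal species with private alleles
#' enriched near five target genes and a mildly elevated damaging-homozygote
#' bias in one sample - and writes every input [runAll()] needs (VCF, GFF3,
#' panel TSV, chromosome-length TSV, YAML config) into `dir`.
#'
#' @param dir output directory.
#' @param seed integer seed (default 1).
#' @return The path to the YAML config, invisibly.
#' @export
writeDemoInputs <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- genomeLayout(c("chr1", "chr2"), c(2000000L, 1000000L))
  tx <- simulateTranscriptome(layout, nGenes = 60L, seed = seed)
  targets <- S4Vectors::mcols(tx)$gene_id[seq_len(5L)]
  cfg <- simulationConfig(
    seed = seed, layout = layout,
    species = data.frame(
      species_id = c("bush_dog", "island_fox", "mainland_fox"),
      n_samples = c(2L, 2L, 2L),
      het_rate = c(4e-4, 5e-4, 1.5e-3)),
    rohPlan = data.frame(sample_id = "island_fox_1", chrom = "chr1",
                         start = 400001L, end = 1600000L),
    focal = "bush_dog", privateRate = 2e-4, targetGenes = targets,
    enrichmentFactor = 12, damagingFraction = 0.25,
    homDamagingBias = c(bush_dog_1 = 2),
    flank = 1000L)
  simulateToDir(cfg, tx, dir)
  yaml::write_yaml(list(
    vcf = "panel.vcf", gff = "transcripts.gff3", panel = "panel.tsv",
    layout = "chrom_lengths.tsv", focal_species = list("bush_dog"),
    window_size = 100000L, window_step = 10000L,
    roh = list(minSnps = 50L), flank = 1000L, alpha = 0.01,
    seed = as.integer(seed)), file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
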