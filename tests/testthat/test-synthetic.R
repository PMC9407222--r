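test_that("zero het rates and no injections give a panel with no heterozygotes", {
  cfg <- simulationConfig(seed = 5, layout = genomeLayout("chr1", 1e6),
                          species = data.frame(species_id = c("a", "b"),
                                               n_samples = 2L, het_rate = 0))
  sim <- simulatePanel(cfg)
  expect_equal(nSites(sim$panel), 0L)
  expect_equal(sum(hetCalls(sim$panel), na.rm = TRUE), 0L)
})

test_that("realized heterozygous site counts follow the configured Poisson rate", {
  ## one species, het_rate 1e-3 on 10 Mb: expected 10,000 het sites per
  ## sample, so realized counts must fall within 3 SD (sqrt(10000) = 100)
  cfg <- simulationConfig(seed = 7, layout = genomeLayout("chr1", 1e7),
                          species = data.frame(species_id = "a",
                                               n_samples = 1L,
                                               het_rate = 1e-3))
  sim <- simulatePanel(cfg)
  n_het <- sum(hetCalls(sim$panel, "a_1"), na.rm = TRUE)
  expect_gt(n_het, 10000 - 3 * 100)
  expect_lt(n_het, 10000 + 3 * 100)
})

test_that("with zero background rate every private allele lies in a target flank", {
  layout <- genomeLayout("chr1", 5e6)
  tx <- simulateTranscriptome(layout, 100L, seed = 3)
  targets <- mcols(tx)$gene_id[seq_len(20L)]
  cfg <- simulationConfig(
    seed = 11, layout = layout,
    species = data.frame(species_id = c("f", "o1", "o2"), n_samples = 2L,
                         het_rate = 1e-4),
    focal = "f", privateRate = 0, targetGenes = targets,
    targetPrivateRate = 0.005)
  sim <- simulatePanel(cfg, tx)
  priv <- isPrivate(sim$panel, "f")
  expect_gt(sum(priv), 50)
  flanks <- buildFlankWindows(tx[mcols(tx)$gene_id %in% targets], 1000L,
                              layout)
  inside <- overlapsAny(variantSites(sim$panel)[priv], flanks)
  expect_true(all(inside))
  expect_setequal(sim$truth@enrichedGeneIds, targets)
})

test_that("truth private counts equal an isPrivate recount of the emitted panel", {
  layout <- genomeLayout(c("chr1", "chr2"), c(2e6, 1e6))
  tx <- simulateTranscriptome(layout, 40L, seed = 2)
  cfg <- simulationConfig(
    seed = 13, layout = layout,
    species = data.frame(species_id = c("f1", "f2", "o"),
                         n_samples = c(2L, 1L, 3L), het_rate = 5e-4),
    focal = c("f1", "f2"), privateRate = 1e-4,
    targetGenes = mcols(tx)$gene_id[1:5], enrichmentFactor = 8,
    damagingFraction = 0.2)
  sim <- simulatePanel(cfg, tx)
  for (f in c("f1", "f2"))
    expect_equal(unname(sim$truth@privateCounts[f]),
                 sum(isPrivate(sim$panel, f)))
  ## truth damaging counts equal the load module's homozygous-derived tally
  load <- damagingLoadAll(sim$panel)
  expect_equal(unname(sim$truth@damagingHomCounts[load$sample_id]),
               as.numeric(load$n_damaging_hom_derived))
})

test_that("identical seed and config produce byte-identical output files", {
  layout <- genomeLayout("chr1", 1e6)
  tx <- simulateTranscriptome(layout, 20L, seed = 9)
  cfg <- simulationConfig(
    seed = 21, layout = layout,
    species = data.frame(species_id = c("a", "b"), n_samples = 2L,
                         het_rate = c(1e-3, 5e-4)),
    focal = "a", privateRate = 5e-5, damagingFraction = 0.3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateToDir(cfg, tx, d1)
  simulateToDir(cfg, tx, d2)
  for (f in c("panel.vcf", "transcripts.gff3", "truth.json",
              "chrom_lengths.tsv", "panel.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("implanted tracts must lie inside their chromosome", {
  cfg <- simulationConfig(
    seed = 5, layout = genomeLayout("chr1", 1e6),
    species = data.frame(species_id = "a", n_samples = 1L, het_rate = 1e-3),
    rohPlan = data.frame(sample_id = "a_1", chrom = "chr1",
                         start = 900001L, end = 1100000L))
  expect_error(simulatePanel(cfg), "outside chromosome bounds")
  cfg2 <- simulationConfig(
    seed = 5, layout = genomeLayout("chr1", 1e6),
    species = data.frame(species_id = "a", n_samples = 1L, het_rate = 1e-3),
    rohPlan = data.frame(sample_id = "a_1", chrom = "chrX",
                         start = 1L, end = 1000L))
  expect_error(simulatePanel(cfg2), "unknown chromosome")
})

test_that("simulated transcriptomes are disjoint with 2-kb gaps and deterministic", {
  layout <- genomeLayout("chr1", 1e7)
  expect_equal(length(simulateTranscriptome(layout, 0L, seed = 1)), 0L)
  tx <- simulateTranscriptome(layout, 50L, seed = 31)
  expect_equal(length(tx), 50L)
  o <- order(start(tx))
  gaps <- start(tx)[o][-1] - end(tx)[o][-50]
  expect_true(all(gaps >= 2000))
  tx2 <- simulateTranscriptome(layout, 50L, seed = 31)
  expect_identical(as.data.frame(tx), as.data.frame(tx2))
  expect_error(simulateTranscriptome(genomeLayout("c", 10000L), 50L, seed = 1),
               "at most")
})
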