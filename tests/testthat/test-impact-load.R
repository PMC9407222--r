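impact_fixture <- function() {
  ## site 1: HIGH, alt private to bush dog       -> counted
  ## site 2: HIGH, alt shared with fox           -> excluded
  ## site 3: MODERATE, alt private to bush dog   -> excluded from HIGH report
  ## site 4: HIGH, alt private to maned wolf     -> other focal species
  panel_from_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "C",
    impact = c("HIGH", "HIGH", "MODERATE", "HIGH"),
    gene = c("gene1", "gene2", "gene3", "gene4"),
    bd_1 = c("0/1", "0/1", "0/1", "0/0"),
    bd_2 = c("0/0", "0/0", "0/0", "0/0"),
    mw_1 = c("0/0", "0/0", "0/0", "1/1"),
    fx_1 = c("0/0", "0/1", "0/0", "0/0")),
    small_species_panel(), small_layout())
}

test_that("unique high-impact reports keep only private HIGH variants", {
  vp <- impact_fixture()
  bd <- uniqueHighImpact(vp, "bush_dog")
  expect_equal(bd$n_variants, 1L)
  expect_equal(bd$genes, "gene1")
  expect_equal(bd$variants$pos, 100L)
  mw <- uniqueHighImpact(vp, "maned_wolf")
  expect_equal(mw$genes, "gene4")
})

test_that("a panel without impact annotations is a hard error", {
  vp <- panel_from_table(data.frame(
    chrom = "chr1", pos = 100L, ref = "A", alt = "C",
    bd_1 = "0/1", bd_2 = "0/0", mw_1 = "0/0", fx_1 = "0/0"),
    small_species_panel(), small_layout())
  expect_error(uniqueHighImpact(vp, "bush_dog"), "impact")
})

test_that("simulated HIGH private variants are recovered gene-for-gene", {
  layout <- genomeLayout("chr1", 2e6)
  tx <- simulateTranscriptome(layout, 60L, seed = 4)
  cfg <- simulationConfig(
    seed = 29, layout = layout,
    species = data.frame(species_id = c("f", "o1", "o2"), n_samples = 2L,
                         het_rate = 2e-4),
    focal = "f", privateRate = 0,
    targetGenes = mcols(tx)$gene_id,
    targetPrivateRate = 3e-4,
    impactProbs = c(HIGH = 1, MODERATE = 0, LOW = 0, MODIFIER = 0))
  sim <- simulatePanel(cfg, tx)
  rep <- uniqueHighImpact(sim$panel, "f")
  ## oracle recount over the emitted panel
  mc <- mcols(variantSites(sim$panel))
  truth_sel <- !is.na(mc$impact) & mc$impact == "HIGH" &
    oracle_private(sim$panel, "f")
  expect_equal(rep$n_variants, sum(truth_sel))
  expect_gt(rep$n_variants, 10)
  expect_setequal(rep$genes, unique(mc$gene_id[truth_sel & !is.na(mc$gene_id)]))
})

test_that("damaging load counts homozygous-derived genotypes with correct polarity", {
  vp <- panel_from_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "C",
    anc = c("A", "C", "A", NA, "A"),
    del = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    bd_1 = c("1/1", "0/0", "0/1", "1/1", "1/1"),
    bd_2 = c("0/0", "1/1", "0/0", "0/0", "0/0"),
    mw_1 = c("0/0", "0/0", "0/0", "0/0", "0/0"),
    fx_1 = c("./.", "0/0", "0/0", "0/0", "0/0")),
    small_species_panel(), small_layout())
  bd1 <- damagingLoad(vp, "bd_1")
  ## site1: 1/1 vs anc=A (ref)   -> hom derived
  ## site2: 0/0 vs anc=C (alt!)  -> hom derived (reference is derived here)
  ## site3: het derived          -> het tally
  ## site4: no ancestral         -> excluded
  ## site5: not deleterious      -> ignored
  expect_equal(bd1$n_damaging_hom_derived, 2L)
  expect_equal(bd1$n_damaging_het, 1L)
  expect_equal(bd1$denominator, 3L)
  expect_equal(bd1$n_excluded_no_ancestral, 1L)
  bd2 <- damagingLoad(vp, "bd_2")
  expect_equal(bd2$n_damaging_hom_derived, 0L)  # site2 1/1 is ancestral hom
  fx <- damagingLoad(vp, "fx_1")
  expect_equal(fx$denominator, 2L)  # missing genotype drops out
})

test_that("load tallies match the brute-force oracle on random panels", {
  for (seed in c(6, 7)) {
    vp <- random_panel(seed, n = 250)
    for (s in sampleIds(vp)) {
      got <- damagingLoad(vp, s)
      want <- oracle_load(vp, s)
      expect_equal(got$n_damaging_hom_derived, want$hom)
      expect_equal(got$n_damaging_het, want$het)
      expect_equal(got$denominator, want$denom)
      expect_equal(got$n_excluded_no_ancestral, want$excluded)
    }
  }
})
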