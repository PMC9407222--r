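test_that("flank windows follow the 1-kb upstream/downstream arithmetic", {
  layout <- genomeLayout("chr1", 30000L)
  tx <- GRanges("chr1", IRanges(10001, 20000), seqinfo = layout)
  mcols(tx) <- DataFrame(gene_id = "gA", transcript_id = "tA")
  fl <- buildFlankWindows(tx, 1000L, layout)
  ## 0-based [9000,10000) and [20000,21000)
  expect_equal(start(fl), c(9001L, 20001L))
  expect_equal(end(fl), c(10000L, 21000L))
})

test_that("flank windows are clipped at chromosome edges", {
  layout <- genomeLayout("chr1", 30000L)
  tx <- GRanges("chr1", IRanges(201, 700), seqinfo = layout)
  mcols(tx) <- DataFrame(gene_id = "gB", transcript_id = "tB")
  fl <- buildFlankWindows(tx, 1000L, layout)
  expect_equal(c(start(fl)[1], end(fl)[1]), c(1L, 200L))  # 0-based [0,200)
  ## transcript filling the whole chromosome: fully clipped, zero-width
  tx2 <- GRanges("chr1", IRanges(1, 30000), seqinfo = layout)
  mcols(tx2) <- DataFrame(gene_id = "gC", transcript_id = "tC")
  fl2 <- buildFlankWindows(tx2, 1000L, layout)
  expect_equal(sum(width(fl2)), 0L)
  expect_equal(unique(mcols(fl2)$gene_id), "gC")
})

test_that("per-gene windows equal the interval-merge oracle on random transcripts", {
  layout <- genomeLayout("chr1", 50000L)
  withr::with_seed(42, {
    for (i in 1:20) {
      st <- sample.int(49000L, 1L)
      en <- min(st + sample.int(3000L, 1L) - 1L, 50000L)
      tx <- GRanges("chr1", IRanges(st, en), seqinfo = layout)
      mcols(tx) <- DataFrame(gene_id = "g", transcript_id = "t")
      fl <- buildFlankWindows(tx, 1000L, layout)
      raw <- IRanges(c(max(st - 1000L, 1L), en + 1L),
                     c(st - 1L, min(en + 1000L, 50000L)))
      want <- reduce(raw, drop.empty.ranges = FALSE)
      if (sum(width(want)) == 0) want <- want[1]
      expect_equal(ranges(fl), want, ignore_attr = TRUE)
    }
  })
})

private_fixture <- function() {
  ## site 1: alt only in bush dog         -> private to bush_dog
  ## site 2: alt in bush dog and fox      -> not private
  ## site 3: alt in bush dog, others miss -> not private (no called non-focal)
  ## site 4: ancestral = alt; ref carried only by bush dog -> private (derived ref)
  ## site 5: alt in maned wolf only       -> private to maned_wolf
  panel_from_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "C",
    anc = c("A", "A", "A", "C", "A"),
    bd_1 = c("0/1", "0/1", "0/1", "0/1", "0/0"),
    bd_2 = c("0/0", "0/0", "0/0", "1/1", "0/0"),
    mw_1 = c("0/0", "0/0", "./.", "1/1", "0/1"),
    fx_1 = c("0/0", "1/1", "./.", "1/1", "0/0")),
    small_species_panel(), small_layout())
}

test_that("private alleles require exclusivity to the focal species", {
  vp <- private_fixture()
  expect_equal(isPrivate(vp, "bush_dog"),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(isPrivate(vp, "maned_wolf"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ## agreement with the brute-force oracle on random panels
  for (seed in c(3, 4)) {
    vp_r <- random_panel(seed, n = 200)
    for (f in c("bush_dog", "maned_wolf", "fox"))
      expect_equal(isPrivate(vp_r, f), oracle_private(vp_r, f))
  }
})

test_that("simulator-injected private sites are all detected and none invented", {
  layout <- genomeLayout("chr1", 2e6)
  cfg <- simulationConfig(
    seed = 19, layout = layout,
    species = data.frame(species_id = c("f", "o1", "o2"),
                         n_samples = c(2L, 2L, 2L), het_rate = 5e-4),
    focal = "f", privateRate = 1e-4)
  sim <- simulatePanel(cfg)
  priv <- isPrivate(sim$panel, "f")
  expect_equal(sum(priv), unname(sim$truth@privateCounts["f"]))
  expect_equal(priv, oracle_private(sim$panel, "f"))
})

test_that("scan results: zero-private genes, clipped genes, sorting, ratio", {
  layout <- genomeLayout("chr1", 100000L)
  tx <- GRanges("chr1", IRanges(c(10001, 1), c(20000, 100000)),
                seqinfo = layout)
  mcols(tx) <- DataFrame(gene_id = c("gA", "gClip"),
                         transcript_id = c("tA", "tClip"))
  fl <- buildFlankWindows(tx, 1000L, layout)
  vp <- panel_from_table(data.frame(
    chrom = "chr1", pos = c(9500L, 9600L, 50000L),
    ref = "A", alt = "C",
    bd_1 = c("0/1", "0/1", "0/0"), bd_2 = "0/0", mw_1 = "0/0",
    fx_1 = c("0/0", "0/0", "0/1")),
    small_species_panel(), small_layout_100k <- layout)
  res <- scanGenes(vp, fl, "bush_dog", panel = small_species_panel(),
                   pType = "exact")
  expect_equal(nrow(res), 2L)
  gA <- res[res$gene_id == "gA", ]
  expect_equal(gA$n_private_focal, 2)
  gC <- res[res$gene_id == "gClip", ]
  expect_equal(gC$n_private_focal, 0)
  expect_equal(gC$p_value, 1)      # fully clipped -> zero counts, p = 1
  expect_equal(gC$ratio, 0)
  expect_false(gC$significant)
  expect_equal(res$gene_id, res$gene_id[order(res$p_value, res$gene_id)])
})

test_that("a gene with zero focal privates has ratio 0 and exact p-value 1", {
  layout <- genomeLayout("chr1", 100000L)
  tx <- GRanges("chr1", IRanges(50001, 52000), seqinfo = layout)
  mcols(tx) <- DataFrame(gene_id = "g0", transcript_id = "t0")
  fl <- buildFlankWindows(tx, 1000L, layout)
  vp <- panel_from_table(data.frame(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "C",
    bd_1 = "0/1", bd_2 = "0/0", mw_1 = "0/0", fx_1 = "0/0"),
    small_species_panel(), layout)
  res <- scanGenes(vp, fl, "bush_dog", pType = "exact")
  expect_equal(res$n_private_focal, 0)
  expect_equal(res$ratio, 0)
  expect_equal(res$p_value, 1)
  ## the mid-P convention stays below 1 but is never significant here
  res_mid <- scanGenes(vp, fl, "bush_dog", pType = "midp")
  expect_lte(res_mid$p_value, 1)
  expect_false(res_mid$significant)
})

test_that("gene-set comparisons compute per-species private proportions", {
  ## one gene; focal has 4 private sites among 16 variable sites in its flanks
  layout <- genomeLayout("chr1", 100000L)
  tx <- GRanges("chr1", IRanges(10001, 12000), seqinfo = layout)
  mcols(tx) <- DataFrame(gene_id = "gA", transcript_id = "tA")
  fl <- buildFlankWindows(tx, 1000L, layout)
  pos <- seq(9100L, by = 50L, length.out = 16L)
  gt_bd <- c(rep("0/1", 4), rep("0/0", 12))
  gt_mw <- c(rep("0/0", 4), rep("0/1", 12))
  gt_fx <- c(rep("0/0", 4), rep("0/1", 12))
  vp <- panel_from_table(data.frame(
    chrom = "chr1", pos = pos, ref = "A", alt = "C",
    bd_1 = gt_bd, bd_2 = "0/0", mw_1 = gt_mw, fx_1 = gt_fx),
    small_species_panel(), layout)
  cmp <- compareGeneSet(vp, fl, "gA")
  expect_equal(cmp$n_variable, rep(16L, 3))
  expect_equal(cmp$proportion[cmp$species_id == "bush_dog"], 0.25)
  expect_equal(cmp$proportion[cmp$species_id == "maned_wolf"], 0)
  expect_error(compareGeneSet(vp, fl, character(0)), "empty")
  expect_error(compareGeneSet(vp, fl, "nope"), "not in flank")
})

test_that("summed per-gene private counts never exceed the genome-wide total", {
  layout <- genomeLayout("chr1", 2e6)
  tx <- simulateTranscriptome(layout, 30L, seed = 8)
  cfg <- simulationConfig(
    seed = 23, layout = layout,
    species = data.frame(species_id = c("f", "o1", "o2"), n_samples = 2L,
                         het_rate = 5e-4),
    focal = "f", privateRate = 2e-4)
  sim <- simulatePanel(cfg, tx)
  fl <- buildFlankWindows(tx, 1000L, layout)
  res <- scanGenes(sim$panel, fl, "f")
  expect_lte(sum(res$n_private_focal), sum(isPrivate(sim$panel, "f")))
})
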