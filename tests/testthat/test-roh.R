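one_sample_panel <- function()
  speciesPanel(data.frame(sample_id = "s_1", species_id = "s"))

## single-sample panel with explicit het/miss patterns on one chromosome
pattern_panel <- function(pos, gt, chrom_len = 2e6) {
  layout <- genomeLayout("chr1", chrom_len)
  panel_from_table(data.frame(chrom = "chr1", pos = pos, ref = "A",
                              alt = "C", s_1 = gt),
                   one_sample_panel(), layout)
}

test_that("a fully homozygous chromosome yields one segment spanning all sites", {
  pos <- seq(1000L, by = 1000L, length.out = 2000L)
  vp <- pattern_panel(pos, rep("0/0", 2000))
  segs <- callROH(vp, "s_1")
  expect_equal(length(segs), 1L)
  expect_equal(start(segs), 1000L)
  expect_equal(end(segs), 2000000L)
  expect_equal(mcols(segs)$n_snps, 2000L)
  expect_equal(as.character(mcols(segs)$length_class), "medium")
})

test_that("alternating het/hom genotypes yield no segments", {
  pos <- seq(1000L, by = 1000L, length.out = 2000L)
  vp <- pattern_panel(pos, rep(c("0/1", "0/0"), 1000))
  expect_equal(length(callROH(vp, "s_1")), 0L)
})

test_that("chromosomes with fewer sites than the scan window are skipped with a warning", {
  vp <- pattern_panel(seq(1000L, by = 1000L, length.out = 10L),
                      rep("0/0", 10))
  expect_warning(segs <- callROH(vp, "s_1"), "skipped")
  expect_equal(length(segs), 0L)
})

test_that("the scanning-window caller matches brute-force enumeration exactly", {
  params <- rohParams(scanSnpCount = 10L, maxHetInScan = 1L,
                      maxMissingInScan = 2L, hitThreshold = 0.05,
                      minSnps = 20L, minLength = 2000, maxGap = 5000)
  for (seed in 1:6) {
    vp <- withr::with_seed(seed, {
      n <- 400L
      pos <- sort(sample.int(500000L, n))
      ## blocks of elevated homozygosity over a noisy het background
      p_het <- rep(0.4, n)
      b1 <- sample.int(n - 150L, 1L)
      p_het[b1:(b1 + 150L)] <- 0.02
      gt <- ifelse(runif(n) < p_het, "0/1", "0/0")
      gt[runif(n) < 0.05] <- "./."
      pattern_panel(pos, gt, chrom_len = 500000L)
    })
    got <- callROH(vp, "s_1", params)
    want <- oracle_roh(vp, "s_1", params)
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      expect_equal(start(got), want$start)
      expect_equal(end(got), want$end)
      expect_equal(mcols(got)$n_snps, want$n_snps)
    }
  }
})

test_that("length classes partition at 0.1 / 1 / 10 Mb with half-open lower bounds", {
  expect_equal(as.character(rohLengthClass(c(5e5, 5e6, 1.2e7, 5e4, 1e6, 1e7))),
               c("short", "medium", "long", NA, "medium", "long"))
  lay <- genomeLayout("c1", 2e8)
  segs <- GRanges("c1", IRanges(c(1, 1e6, 5e7),
                                width = c(5e5, 5e6, 1.2e7)))
  sm <- classifyAndSummarize(segs, lay)
  expect_equal(sm$per_class$n_segments, c(1L, 1L, 1L))
  expect_equal(sm$per_class$summed_bp, c(5e5, 5e6, 1.2e7))
  expect_equal(sm$froh, (5e5 + 5e6 + 1.2e7) / 2e8)
  expect_equal(sm$n_discarded, 0L)
})

test_that("summaries handle empty input and reproduce simple arithmetic", {
  lay <- genomeLayout("c1", 1e8)
  empty <- GRanges(seqinfo = GenomeInfoDb::Seqinfo("c1", 1e8))
  sm0 <- classifyAndSummarize(empty, lay)
  expect_equal(sm0$per_class$n_segments, c(0L, 0L, 0L))
  expect_equal(sm0$froh, 0)
  ## 26 segments of 1 Mb on a 100-Mb genome: medium count 26, F_ROH 0.26
  segs <- GRanges("c1", IRanges(seq(1, by = 2e6, length.out = 26),
                                width = 1e6))
  sm <- classifyAndSummarize(segs, lay)
  expect_equal(sm$per_class$n_segments[2], 26L)
  expect_equal(sm$froh, 0.26)
  ## sub-0.1-Mb segments are discarded and tallied
  tiny <- GRanges("c1", IRanges(c(1, 1e6), width = c(5e4, 2e5)))
  smt <- classifyAndSummarize(tiny, lay)
  expect_equal(smt$n_discarded, 1L)
  expect_equal(smt$per_class$n_segments[1], 1L)
})

test_that("raising the hit threshold never increases total ROH length", {
  vp <- withr::with_seed(99, {
    n <- 500L
    pos <- sort(sample.int(800000L, n))
    p_het <- rep(0.3, n)
    p_het[100:260] <- 0.01
    gt <- ifelse(runif(n) < p_het, "0/1", "0/0")
    pattern_panel(pos, gt, chrom_len = 800000L)
  })
  params <- function(th) rohParams(scanSnpCount = 10L, maxHetInScan = 1L,
                                   maxMissingInScan = 2L, hitThreshold = th,
                                   minSnps = 20L, minLength = 2000,
                                   maxGap = 1e6)
  totals <- vapply(c(0.05, 0.2, 0.5, 0.8, 1),
                   function(th) sum(width(callROH(vp, "s_1", params(th)))),
                   numeric(1))
  expect_true(all(diff(totals) <= 0))
})
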