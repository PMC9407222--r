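suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

small_layout <- function() genomeLayout(c("chr1", "chr2"), c(100000L, 50000L))

small_species_panel <- function() {
  speciesPanel(data.frame(
    sample_id = c("bd_1", "bd_2", "mw_1", "fx_1"),
    species_id = c("bush_dog", "bush_dog", "maned_wolf", "fox")),
    focal = c("bush_dog", "maned_wolf"))
}

## build a VariantPanel from a compact site table; gt columns are strings
## like "0/1", "./.", "1/2"
panel_from_table <- function(tab, panel, layout) {
  ids <- sampleIds(panel)
  gt1 <- gt2 <- matrix(NA_integer_, nrow(tab), length(ids),
                       dimnames = list(NULL, ids))
  for (s in ids) {
    g <- tab[[s]]
    a1 <- suppressWarnings(as.integer(sub("/.*", "", g)))
    a2 <- suppressWarnings(as.integer(sub(".*/", "", g)))
    gt1[, s] <- a1
    gt2[, s] <- a2
  }
  sites <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L), seqinfo = layout)
  mcols(sites) <- DataFrame(
    ref = tab$ref, alt = CharacterList(strsplit(tab$alt, ",")),
    ancestral = if (!is.null(tab$anc)) tab$anc else NA_character_,
    impact = if (!is.null(tab$impact)) tab$impact else NA_character_,
    deleterious = if (!is.null(tab$del)) tab$del else NA,
    gene_id = if (!is.null(tab$gene)) tab$gene else NA_character_)
  VariantPanel(sites, gt1, gt2, panel)
}

## random small panel (independent of the simulator) for oracle-equivalence
## checks: biallelic + occasional multiallelic sites, missingness, random
## annotations
random_panel <- function(seed, n = 300) {
  withr::with_seed(seed, {
    layout <- small_layout()
    panel <- small_species_panel()
    ids <- sampleIds(panel)
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE,
                         prob = c(0.7, 0.3)))
    pos <- c(sort(sample.int(100000L, sum(chrom == "chr1"))),
             sort(sample.int(50000L, sum(chrom == "chr2"))))
    multi <- runif(n) < 0.1
    bases <- c("A", "C", "G", "T")
    perm <- t(vapply(seq_len(n), function(i) sample(bases, 4L),
                     character(4)))
    ref <- perm[, 1]
    alt <- ifelse(multi, paste(perm[, 2], perm[, 3], sep = ","), perm[, 2])
    n_all <- ifelse(multi, 3L, 2L)
    gt1 <- gt2 <- matrix(NA_integer_, n, length(ids),
                         dimnames = list(NULL, ids))
    for (s in ids) {
      a1 <- vapply(n_all, function(k) sample.int(k, 1L) - 1L, integer(1))
      a2 <- vapply(n_all, function(k) sample.int(k, 1L) - 1L, integer(1))
      miss <- runif(n) < 0.08
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      gt1[, s] <- a1; gt2[, s] <- a2
    }
    anc <- ifelse(runif(n) < 0.6, ref, NA_character_)
    swap <- runif(n) < 0.15
    anc[swap] <- perm[swap, 2]   # alternate allele ancestral
    none <- runif(n) < 0.05
    anc[none] <- perm[none, 4]   # ancestral matches no sampled allele
    impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER", NA), n,
                     replace = TRUE, prob = c(.1, .15, .2, .35, .2))
    del <- sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                  prob = c(.25, .55, .2))
    gene <- sample(c(paste0("g", 1:8), NA), n, replace = TRUE)
    sites <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = layout)
    mcols(sites) <- DataFrame(ref = ref,
                              alt = CharacterList(strsplit(alt, ",")),
                              ancestral = anc, impact = impact,
                              deleterious = del, gene_id = gene)
    VariantPanel(sites, gt1, gt2, panel)
  })
}
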