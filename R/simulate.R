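## Multi-species diploid genotype simulator. Sites are independent (no
## linkage): every downstream statistic in this package is site-wise, so an
## independent-site process keeps the recovery oracles exact. Private alleles
## are injected as derived singletons confined to one focal species by
## construction; background heterozygous variants are shared with samples of
## two other species (as homozygous-alternate carriers, which leaves their
## heterozygosity untouched) so that they can never masquerade as private.

#' Build a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param layout genome layout (`Seqinfo`).
#' @param species data.frame with columns `species_id`, `n_samples`,
#'   `het_rate` (expected heterozygous sites per bp per sample). Sample ids
#'   are `<species_id>_<k>`.
#' @param rohPlan optional data.frame of autozygous tracts to implant:
#'   columns `sample_id`, `chrom`, `start`, `end` (1-based inclusive); tracts
#'   must lie within chromosome bounds and not overlap within a sample.
#' @param focal focal species ids receiving injected private alleles.
#' @param privateRate expected private alleles per bp per focal species.
#' @param targetGenes gene ids whose flanking windows get
#'   `enrichmentFactor` times the background private rate.
#' @param enrichmentFactor multiplier (>= 1) on `privateRate` inside target
#'   flanks.
#' @param targetPrivateRate optional absolute private rate (per bp) inside
#'   target flanks, overriding `enrichmentFactor * privateRate`; allows the
#'   degenerate zero-background design where every private allele falls in a
#'   target flank.
#' @param damagingFraction probability an injected derived allele is flagged
#'   deleterious.
#' @param homDamagingBias named numeric: per-sample multiplier on the base
#'   probability 0.5 that a deleterious derived allele is carried homozygous
#'   (unlisted samples use 1).
#' @param impactProbs named probabilities over impact categories assigned to
#'   injected private alleles.
#' @param flank flank width (bp) defining target-gene windows.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed, layout, species, rohPlan = NULL,
                             focal = character(), privateRate = 0,
                             targetGenes = character(),
                             enrichmentFactor = 1,
                             targetPrivateRate = NA_real_,
                             damagingFraction = 0,
                             homDamagingBias = NULL,
                             impactProbs = c(HIGH = 0.05, MODERATE = 0.15,
                                             LOW = 0.2, MODIFIER = 0.6),
                             flank = 1000L) {
  if (is.null(rohPlan))
    rohPlan <- data.frame(sample_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0))
  if (is.null(homDamagingBias)) homDamagingBias <- stats::setNames(numeric(0),
                                                                   character(0))
  new("SimulationConfig", seed = as.integer(seed), layout = layout,
      species = species, rohPlan = rohPlan, focal = as.character(focal),
      privateRate = privateRate, targetGenes = as.character(targetGenes),
      enrichmentFactor = enrichmentFactor,
      targetPrivateRate = targetPrivateRate,
      damagingFraction = damagingFraction,
      homDamagingBias = homDamagingBias, impactProbs = impactProbs,
      flank = as.integer(flank))
}

#' Sample ids implied by a simulation configuration
#' @param config a [SimulationConfig-class].
#' @return Character vector `<species_id>_<k>` in species-table order.
#' @export
simSampleIds <- function(config) {
  sp <- config@species
  unlist(lapply(seq_len(nrow(sp)), function(i)
    paste0(sp$species_id[i], "_", seq_len(sp$n_samples[i]))))
}

.sim_panel_of <- function(config) {
  sp <- config@species
  speciesPanel(data.frame(
    sample_id = simSampleIds(config),
    species_id = rep(sp$species_id, sp$n_samples)), focal = config@focal)
}

.check_roh_plan <- function(plan, layout, sample_ids) {
  if (!nrow(plan)) return(invisible(TRUE))
  lens <- GenomeInfoDb::seqlengths(layout)
  bad_chr <- !(plan$chrom %in% GenomeInfoDb::seqnames(layout))
  if (any(bad_chr))
    stop("roh plan tract on unknown chromosome: ",
         plan$chrom[which(bad_chr)[1]])
  lim <- lens[plan$chrom]
  out <- plan$start < 1 | plan$end > lim | plan$start > plan$end
  if (any(out))
    stop("roh plan tract outside chromosome bounds: ",
         plan$sample_id[which(out)[1]], " ", plan$chrom[which(out)[1]], ":",
         plan$start[which(out)[1]], "-", plan$end[which(out)[1]])
  if (any(!(plan$sample_id %in% sample_ids)))
    stop("roh plan names unknown sample: ",
         setdiff(plan$sample_id, sample_ids)[1])
  for (s in unique(plan$sample_id)) {
    p <- plan[plan$sample_id == s, ]
    for (ch in unique(p$chrom)) {
      q <- p[p$chrom == ch, ]
      q <- q[order(q$start), ]
      if (nrow(q) > 1 && any(q$start[-1] <= q$end[-nrow(q)]))
        stop("overlapping implanted tracts for sample ", s, " on ", ch)
    }
  }
  invisible(TRUE)
}

#' Simulate a multi-species genotype panel with exact truth
#'
#' Generates per-species polymorphic sites as a homogeneous point process so
#' that each sample's expected heterozygosity per bp equals its species'
#' `het_rate`; forces homozygosity inside implanted autozygous tracts;
#' injects lineage-private derived alleles at `privateRate` per bp
#' (multiplied by `enrichmentFactor` inside the flanking windows of
#' `targetGenes`); flags injected alleles deleterious with probability
#' `damagingFraction` and makes flagged alleles homozygous in their carrier
#' with probability `min(1, 0.5 * homDamagingBias[carrier])`. The ancestral
#' allele (= REF) is recorded at every simulated site. Identical seed and
#' configuration yield identical output, byte-for-byte once written.
#'
#' Truth counts (per-species private sites, per-sample damaging homozygous
#' derived genotypes) are recomputed from the emitted genotype matrix, not
#' taken from the configuration.
#'
#' @param config a [SimulationConfig-class].
#' @param transcripts transcript models (GRanges with `gene_id`,
#'   `transcript_id`), required when `targetGenes` is non-empty; also used to
#'   annotate sites falling in gene bodies or flanks with `gene_id`.
#' @return `list(panel = VariantPanel, truth = SimTruth)`.
#' @export
simulatePanel <- function(config, transcripts = NULL) {
  panel <- .sim_panel_of(config)
  ids <- sampleIds(panel)
  .check_roh_plan(config@rohPlan, config@layout, ids)
  if (length(config@targetGenes)) {
    if (is.null(transcripts))
      stop("transcripts required when targetGenes is non-empty")
    missing_g <- setdiff(config@targetGenes,
                         S4Vectors::mcols(transcripts)$gene_id)
    if (length(missing_g))
      stop("target gene(s) not in transcripts: ",
           paste(missing_g, collapse = ", "))
  }
  withr::with_seed(config@seed, .simulate_panel_impl(config, transcripts,
                                                     panel))
}

.simulate_panel_impl <- function(config, transcripts, panel) {
  layout <- config@layout
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  sp <- config@species
  ids <- sampleIds(panel)
  sp_of <- stats::setNames(panel@samples$species_id, ids)
  cols_of <- lapply(stats::setNames(sp$species_id, sp$species_id),
                    function(s) which(sp_of == s))

  ## -- draw site positions -------------------------------------------------
  chr <- character(0); pos <- integer(0); kind <- character(0)
  site_sp <- character(0)
  for (ci in seq_along(chroms)) {
    L <- as.numeric(lens[ci])
    for (si in seq_len(nrow(sp))) {
      n <- stats::rpois(1, sp$het_rate[si] * L)
      if (n > 0) {
        chr <- c(chr, rep(chroms[ci], n))
        pos <- c(pos, sample.int(L, n))
        kind <- c(kind, rep("het", n))
        site_sp <- c(site_sp, rep(sp$species_id[si], n))
      }
    }
  }
  for (f in config@focal) {
    for (ci in seq_along(chroms)) {
      L <- as.numeric(lens[ci])
      n <- stats::rpois(1, config@privateRate * L)
      if (n > 0) {
        chr <- c(chr, rep(chroms[ci], n))
        pos <- c(pos, sample.int(L, n))
        kind <- c(kind, rep("priv", n))
        site_sp <- c(site_sp, rep(f, n))
      }
    }
  }
  extra_rate <- if (!is.na(config@targetPrivateRate))
    config@targetPrivateRate - config@privateRate
  else (config@enrichmentFactor - 1) * config@privateRate
  if (length(config@targetGenes) && extra_rate > 0) {
    tg <- transcripts[S4Vectors::mcols(transcripts)$gene_id %in%
                        config@targetGenes]
    fl <- buildFlankWindows(tg, flank = config@flank, layout = layout)
    for (f in config@focal) {
      for (wi in seq_along(fl)) {
        w <- BiocGenerics::width(fl)[wi]
        n <- stats::rpois(1, extra_rate * w)
        if (n > 0) {
          chr <- c(chr, rep(as.character(GenomeInfoDb::seqnames(fl))[wi], n))
          pos <- c(pos, BiocGenerics::start(fl)[wi] - 1L + sample.int(w, n))
          kind <- c(kind, rep("priv", n))
          site_sp <- c(site_sp, rep(f, n))
        }
      }
    }
  }

  ## -- deduplicate colliding positions (first process wins) ---------------
  keep <- if (length(pos)) !duplicated(paste0(chr, ":", pos)) else logical(0)
  chr <- chr[keep]; pos <- pos[keep]; kind <- kind[keep]
  site_sp <- site_sp[keep]
  n_sites <- length(pos)

  ## -- genotypes -----------------------------------------------------------
  gt1 <- matrix(0L, n_sites, length(ids), dimnames = list(NULL, ids))
  gt2 <- gt1
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, n_sites, replace = TRUE)]
  alt1 <- bases[(match(ref, bases) - 1L +
                   sample.int(3L, n_sites, replace = TRUE)) %% 4L + 1L]
  impact <- rep(NA_character_, n_sites)
  delet <- rep(FALSE, n_sites)

  het_rows <- which(kind == "het")
  if (length(het_rows)) {
    for (s in sp$species_id) {
      rows <- het_rows[site_sp[het_rows] == s]
      if (length(rows)) gt2[rows, cols_of[[s]]] <- 1L
    }
    ## homozygous-alternate sharers in up to two other species
    all_sp <- sp$species_id
    for (s in all_sp) {
      rows <- het_rows[site_sp[het_rows] == s]
      others <- setdiff(all_sp, s)
      if (!length(rows) || !length(others)) next
      k <- length(others)
      i1 <- sample.int(k, length(rows), replace = TRUE)
      sharer_sp <- list(others[i1])
      if (k >= 2L) {
        j <- sample.int(k - 1L, length(rows), replace = TRUE)
        i2 <- j + (j >= i1)
        sharer_sp <- c(sharer_sp, list(others[i2]))
      }
      for (ss in sharer_sp) {
        col <- vapply(seq_along(rows), function(i) {
          cs <- cols_of[[ss[i]]]
          cs[sample.int(length(cs), 1L)]
        }, integer(1))
        idx <- cbind(rows, col)
        gt1[idx] <- 1L
        gt2[idx] <- 1L
      }
    }
  }

  priv_rows <- which(kind == "priv")
  if (length(priv_rows)) {
    bias <- rep(1, length(ids))
    names(bias) <- ids
    bias[names(config@homDamagingBias)] <- config@homDamagingBias
    for (f in config@focal) {
      rows <- priv_rows[site_sp[priv_rows] == f]
      if (!length(rows)) next
      cs <- cols_of[[f]]
      carrier <- cs[sample.int(length(cs), length(rows), replace = TRUE)]
      is_del <- stats::runif(length(rows)) < config@damagingFraction
      p_hom <- ifelse(is_del, pmin(1, 0.5 * bias[carrier]), 0.5)
      is_hom <- stats::runif(length(rows)) < p_hom
      idx <- cbind(rows, carrier)
      gt1[idx] <- ifelse(is_hom, 1L, 0L)
      gt2[idx] <- 1L
      delet[rows] <- is_del
      impact[rows] <- sample(names(config@impactProbs), length(rows),
                             replace = TRUE, prob = config@impactProbs)
    }
  }

  ## -- implant autozygous tracts (forced homozygous-reference) -------------
  plan <- config@rohPlan
  for (i in seq_len(nrow(plan))) {
    rows <- which(chr == plan$chrom[i] & pos >= plan$start[i] &
                    pos <= plan$end[i])
    gt1[rows, plan$sample_id[i]] <- 0L
    gt2[rows, plan$sample_id[i]] <- 0L
  }

  ## -- assemble ------------------------------------------------------------
  gene_id <- rep(NA_character_, n_sites)
  sites <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos),
                                  seqinfo = layout)
  if (!is.null(transcripts) && length(transcripts)) {
    reg <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(transcripts,
                            BiocGenerics::width(transcripts) +
                              2L * config@flank, fix = "center")))
    ov <- GenomicRanges::findOverlaps(sites, reg, select = "first")
    hit <- !is.na(ov)
    gene_id[hit] <- S4Vectors::mcols(transcripts)$gene_id[ov[hit]]
  }
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    ref = ref, alt = IRanges::CharacterList(as.list(alt1)),
    ancestral = ref, impact = impact, deleterious = delet,
    gene_id = gene_id)
  vp <- VariantPanel(sites, gt1, gt2, panel)

  truth <- .recount_truth(vp, config)
  list(panel = vp, truth = truth)
}

## Truth is recomputed from the emitted genotypes with direct matrix scans.
.recount_truth <- function(vp, config) {
  panel <- samplePanel(vp)
  ids <- sampleIds(panel)
  sp_of <- stats::setNames(panel@samples$species_id, ids)
  species <- unique(panel@samples$species_id)
  carries_alt <- (vp@gt1 == 1L) | (vp@gt2 == 1L)
  carries_alt[is.na(carries_alt)] <- FALSE
  called <- !is.na(vp@gt1)
  by_sp <- vapply(species, function(s)
    rowSums(carries_alt[, sp_of == s, drop = FALSE]) > 0,
    logical(nrow(carries_alt)))
  priv_counts <- vapply(config@focal, function(f) {
    others <- species != f
    called_other <- rowSums(called[, sp_of != f, drop = FALSE]) > 0
    sum(by_sp[, f] & rowSums(by_sp[, others, drop = FALSE]) == 0 &
          called_other)
  }, numeric(1))
  mc <- S4Vectors::mcols(vp@sites)
  del <- !is.na(mc$deleterious) & mc$deleterious & !is.na(mc$ancestral)
  hom_derived <- (vp@gt1 == vp@gt2) & (vp@gt1 != 0L)  # ancestral == REF here
  hom_derived[is.na(hom_derived)] <- FALSE
  dam <- colSums(hom_derived[del, , drop = FALSE])
  plan <- config@rohPlan
  implanted <- if (nrow(plan))
    GenomicRanges::GRanges(plan$chrom,
                           IRanges::IRanges(plan$start, plan$end),
                           sample_id = plan$sample_id,
                           seqinfo = config@layout)
  else GenomicRanges::GRanges(sample_id = character(0),
                              seqinfo = config@layout)
  new("SimTruth", implantedROH = implanted,
      enrichedGeneIds = if ((!is.na(config@targetPrivateRate) &&
                               config@targetPrivateRate > config@privateRate) ||
                            (is.na(config@targetPrivateRate) &&
                               config@enrichmentFactor > 1 &&
                               config@privateRate > 0))
        config@targetGenes else character(0),
      privateCounts = priv_counts,
      damagingHomCounts = stats::setNames(as.numeric(dam), ids),
      nSites = nSites(vp))
}

#' Simulate a non-overlapping transcriptome
#'
#' Places `nGenes` gene bodies (one transcript each) uniformly within
#' per-chromosome slots so that bodies plus `margin`-bp flanks never overlap
#' (pairwise gap at least `2 * margin`). Deterministic under `seed`.
#'
#' @param layout genome layout (`Seqinfo`).
#' @param nGenes number of genes.
#' @param seed integer RNG seed.
#' @param geneLength integer range of gene body lengths (bp).
#' @param margin reserved flank per gene side (bp), default 1 kb.
#' @return GRanges with mcols `gene_id`, `transcript_id`; strands random.
#' @export
simulateTranscriptome <- function(layout, nGenes, seed,
                                  geneLength = c(500L, 1500L),
                                  margin = 1000L) {
  lens <- as.numeric(GenomeInfoDb::seqlengths(layout))
  chroms <- GenomeInfoDb::seqnames(layout)
  nGenes <- as.integer(nGenes)
  if (nGenes == 0L) {
    empty <- GenomicRanges::GRanges(seqinfo = layout)
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      gene_id = character(0), transcript_id = character(0))
    return(empty)
  }
  need <- max(geneLength) + 2 * margin + 2
  max_feasible <- sum(floor(lens / need))
  if (nGenes > max_feasible)
    stop("layout too small for ", nGenes, " genes; at most ", max_feasible,
         " fit with bodies up to ", max(geneLength), " bp and ", margin,
         "-bp flanks")
  ## proportional allocation, remainders to the largest fractional parts
  raw <- nGenes * lens / sum(lens)
  n_per <- floor(raw)
  rem <- nGenes - sum(n_per)
  if (rem > 0) {
    o <- order(raw - n_per, decreasing = TRUE)
    n_per[o[seq_len(rem)]] <- n_per[o[seq_len(rem)]] + 1
  }
  ## rebalance chromosomes that cannot host their share
  cap <- floor(lens / need)
  over <- pmax(n_per - cap, 0)
  if (sum(over) > 0) {
    n_per <- pmin(n_per, cap)
    slack_order <- order(cap - n_per, decreasing = TRUE)
    i <- 1L
    while (sum(n_per) < nGenes) {
      ci <- slack_order[i %% length(lens) + 1L]
      if (n_per[ci] < cap[ci]) n_per[ci] <- n_per[ci] + 1
      i <- i + 1L
    }
  }
  withr::with_seed(seed, {
    out <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      n <- n_per[ci]
      if (n == 0) next
      slot <- floor(lens[ci] / n)
      glen <- sample(seq(min(geneLength), max(geneLength)), n, replace = TRUE)
      slack <- slot - glen - 2 * margin
      offset <- floor(stats::runif(n) * (slack + 1))
      start <- (seq_len(n) - 1) * slot + margin + offset + 1
      gr <- GenomicRanges::GRanges(chroms[ci],
                                   IRanges::IRanges(start = start,
                                                    width = glen),
                                   strand = sample(c("+", "-"), n,
                                                   replace = TRUE),
                                   seqinfo = layout)
      idx <- gi + seq_len(n)
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = sprintf("g%05d", idx),
        transcript_id = sprintf("t%05d", idx))
      gi <- gi + n
      out[[length(out) + 1L]] <- gr
    }
    do.call(c, out)
  })
}

#' Write simulated panel, annotation and truth to a directory
#'
#' Emits `panel.vcf`, `transcripts.gff3`, `chrom_lengths.tsv`, `panel.tsv`
#' and `truth.json`. Re-running with the same configuration produces
#' byte-identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param transcripts transcript models (may be NULL when unused).
#' @param dir output directory (created if needed).
#' @return Invisibly, the list returned by [simulatePanel()].
#' @export
simulateToDir <- function(config, transcripts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePanel(config, transcripts)
  writeVariantPanel(sim$panel, file.path(dir, "panel.vcf"),
                    seed = config@seed)
  if (!is.null(transcripts))
    writeTranscriptsGFF3(transcripts, file.path(dir, "transcripts.gff3"))
  writeGenomeLayout(config@layout, file.path(dir, "chrom_lengths.tsv"))
  p <- samplePanel(sim$panel)@samples
  writeLines(c("sample_id\tspecies_id",
               paste(p$sample_id, p$species_id, sep = "\t")),
             file.path(dir, "panel.tsv"))
  writeSimTruth(sim$truth, file.path(dir, "truth.json"))
  invisible(sim)
}

#' Write a SimTruth to JSON
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  roh <- data.frame(
    sample_id = S4Vectors::mcols(truth@implantedROH)$sample_id,
    chrom = as.character(GenomeInfoDb::seqnames(truth@implantedROH)),
    start = BiocGenerics::start(truth@implantedROH),
    end = BiocGenerics::end(truth@implantedROH))
  jsonlite::write_json(list(
    implanted_roh = roh,
    enriched_gene_ids = truth@enrichedGeneIds,
    private_counts = as.list(truth@privateCounts),
    damaging_hom_counts = as.list(truth@damagingHomCounts),
    n_sites = truth@nSites), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", object@nSites, "sites;",
      length(object@implantedROH), "implanted tracts;",
      length(object@enrichedGeneIds), "enriched genes\n")
  if (length(object@privateCounts)) {
    cat("  private counts:",
        paste(names(object@privateCounts), object@privateCounts,
              sep = "=", collapse = ", "), "\n")
  }
})
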