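#' Build regulatory flanking windows for transcripts
#'
#' Per transcript (1-based body [start, end]), the upstream window covers the
#' `flank` bases immediately before the start site and the downstream window
#' the `flank` bases immediately after the end site; both are clipped to
#' chromosome bounds, and the pair is merged into a single window in the
#' degenerate case where the clipped windows overlap or touch.
#'
#' @param transcripts GRanges of transcript models (one per gene; apply
#'   [longestIsoforms()] first when a gene has several).
#' @param flank flank width in bp (default 1000, the 1-kb promoter/terminator
#'   proxy).
#' @param layout genome layout (`Seqinfo`); defaults to the seqinfo of
#'   `transcripts`.
#' @return GRanges of flank windows with mcols `gene_id`, `transcript_id`;
#'   one or two ranges per gene.
#' @export
buildFlankWindows <- function(transcripts, flank = 1000L, layout = NULL) {
  if (is.null(layout)) layout <- GenomeInfoDb::seqinfo(transcripts)
  if (!length(transcripts)) {
    empty <- GenomicRanges::GRanges(seqinfo = layout)
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      gene_id = character(0), transcript_id = character(0))
    return(empty)
  }
  mc <- S4Vectors::mcols(transcripts)
  chrom <- as.character(GenomeInfoDb::seqnames(transcripts))
  st <- BiocGenerics::start(transcripts)
  en <- BiocGenerics::end(transcripts)
  lens <- GenomeInfoDb::seqlengths(layout)[chrom]
  up <- IRanges::IRanges(pmax(st - flank, 1L), pmax(st - 1L, 0L))
  down <- IRanges::IRanges(en + 1L, pmin(en + flank, lens))
  out <- lapply(seq_along(transcripts), function(i) {
    rr <- c(up[i], down[i])
    ## merge when overlapping/adjacent; a fully clipped pair collapses to one
    ## zero-width window so the gene still appears in scan reports
    rr <- IRanges::reduce(rr, drop.empty.ranges = FALSE)
    if (sum(BiocGenerics::width(rr)) == 0) rr <- rr[1]
    g <- GenomicRanges::GRanges(chrom[i], rr, seqinfo = layout)
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      gene_id = rep(mc$gene_id[i], length(rr)),
      transcript_id = rep(mc$transcript_id[i], length(rr)))
    g
  })
  do.call(c, out[!vapply(out, is.null, logical(1))])
}

#' Sites carrying an allele private to one species
#'
#' A site is private to `focal` iff some alternate allele (restricted to
#' derived alleles, i.e. differing from the ancestral allele, when the
#' ancestral allele is known) is carried by at least one focal-species sample
#' and by zero samples of every other species with a called genotype. Sites
#' where all non-focal genotypes are missing are never private.
#'
#' @param x a [VariantPanel-class].
#' @param focal a species id.
#' @param panel a [SpeciesPanel-class] (defaults to the panel of `x`).
#' @return Logical vector over the sites of `x`.
#' @export
isPrivate <- function(x, focal, panel = samplePanel(x)) {
  ids <- sampleIds(panel)
  sp_of <- stats::setNames(panel@samples$species_id, ids)
  if (!focal %in% sp_of) stop("unknown species: ", focal)
  fc <- ids[sp_of == focal]
  nf <- ids[sp_of != focal]
  mc <- S4Vectors::mcols(x@sites)
  n <- nSites(x)
  if (!n) return(logical(0))
  anc_idx <- .ancestral_index(x)
  has_anc <- !is.na(mc$ancestral)
  n_alt <- lengths(mc$alt)
  called_nf <- rowSums(!is.na(x@gt1[, nf, drop = FALSE])) > 0
  priv <- rep(FALSE, n)
  g1f <- x@gt1[, fc, drop = FALSE]; g2f <- x@gt2[, fc, drop = FALSE]
  g1n <- x@gt1[, nf, drop = FALSE]; g2n <- x@gt2[, nf, drop = FALSE]
  for (a in 0:max(c(n_alt, 0))) {
    ## candidate alleles: any allele differing from the ancestral allele when
    ## polarization is available, otherwise any alternate allele
    exists_a <- if (a == 0L) rep(TRUE, n) else n_alt >= a
    candidate <- exists_a &
      ifelse(has_anc, is.na(anc_idx) | anc_idx != a, a > 0L)
    if (!any(candidate)) next
    cf <- (g1f == a) | (g2f == a)
    cf[is.na(cf)] <- FALSE
    cn <- (g1n == a) | (g2n == a)
    cn[is.na(cn)] <- FALSE
    priv <- priv | (candidate & rowSums(cf) > 0 & rowSums(cn) == 0)
  }
  priv & called_nf
}

## sites variable within one species: >= 1 heterozygous or non-reference
## called genotype among that species' samples
.variable_in_species <- function(x, species, panel = samplePanel(x)) {
  ids <- sampleIds(panel)
  cols <- ids[panel@samples$species_id == species]
  g1 <- x@gt1[, cols, drop = FALSE]; g2 <- x@gt2[, cols, drop = FALSE]
  v <- (g1 != g2) | (g1 != 0L) | (g2 != 0L)
  v[is.na(v)] <- FALSE
  rowSums(v) > 0
}

#' Scan gene flanking windows for focal-lineage private-allele enrichment
#'
#' For every gene, counts the focal species' private alleles in its flanking
#' windows and the average number of sites variable within each background
#' species over the same windows, forms the ratio
#' `n_private_focal / max(mean_variable_other, pseudocount)`, and assigns a
#' one-sided P value for an excess of private alleles against one of three
#' nulls. The default analytic null is Poisson: under homogeneity the private
#' count in a gene's windows has expectation genome-wide focal private rate
#' (per bp) times the gene's flank length. A binomial null (flank length
#' trials at the per-bp rate) and an empirical permutation null that re-draws
#' `nPerm` windows of the gene's total flank length uniformly from the genome
#' are also available.
#'
#' For the analytic nulls, `pType` selects the convention for the discrete
#' tail probability: `"midp"` (default) reports `P(X > x) + P(X = x)/2`,
#' the standard calibration-preserving choice for discrete tests while
#' remaining deterministic; `"exact"` reports `P(X >= x)` (conservative);
#' `"randomized"` reports the randomized PIT `P(X > x) + U * P(X = x)`,
#' which is exactly Uniform(0,1) under the null and is intended for
#' calibration diagnostics, not for reporting.
#'
#' @param x a [VariantPanel-class].
#' @param flanks GRanges of flank windows from [buildFlankWindows()].
#' @param focal focal species id.
#' @param panel a [SpeciesPanel-class] (defaults to the panel of `x`).
#' @param alpha significance level on the raw P value (default 0.01).
#' @param pseudocount floor of the ratio denominator (default 1).
#' @param null `"poisson"` (default), `"binomial"` or `"permutation"`.
#' @param nPerm permutation count (default 10000).
#' @param pType tail convention for the analytic nulls: `"midp"` (default),
#'   `"exact"` or `"randomized"`.
#' @param adjust `"none"` (default; raw P values, as in reporting "P < 0.01")
#'   or `"BH"` for Benjamini-Hochberg FDR, which then also drives
#'   `significant`.
#' @param seed optional seed for the randomized conventions (permutation
#'   null, randomized PIT).
#' @return data.frame with one row per gene: gene_id, flank_bp,
#'   n_private_focal, mean_variable_other, ratio, p_value (plus q_value when
#'   `adjust = "BH"`), significant; sorted by p_value then gene_id. Genes
#'   whose windows were fully clipped away get zero counts and p_value 1.
#' @export
scanGenes <- function(x, flanks, focal, panel = samplePanel(x),
                      alpha = 0.01, pseudocount = 1,
                      null = c("poisson", "binomial", "permutation"),
                      nPerm = 10000L, pType = c("midp", "exact", "randomized"),
                      adjust = c("none", "BH"), seed = NULL) {
  null <- match.arg(null)
  pType <- match.arg(pType)
  adjust <- match.arg(adjust)
  genes <- unique(S4Vectors::mcols(flanks)$gene_id)
  gidx <- match(S4Vectors::mcols(flanks)$gene_id, genes)
  flank_bp <- as.numeric(rowsum(as.numeric(BiocGenerics::width(flanks)),
                                gidx)[, 1])
  priv <- isPrivate(x, focal, panel)
  priv_gr <- x@sites[priv]
  ov <- GenomicRanges::findOverlaps(flanks, priv_gr)
  n_priv <- as.numeric(rowsum(
    c(tabulate(S4Vectors::queryHits(ov), nbins = length(flanks))), gidx)[, 1])

  others <- setdiff(unique(panel@samples$species_id), focal)
  var_counts <- matrix(0, length(genes), length(others))
  for (k in seq_along(others)) {
    v <- .variable_in_species(x, others[k], panel)
    ovv <- GenomicRanges::findOverlaps(flanks, x@sites[v])
    var_counts[, k] <- as.numeric(rowsum(
      c(tabulate(S4Vectors::queryHits(ovv), nbins = length(flanks))),
      gidx)[, 1])
  }
  mean_var <- if (length(others)) rowMeans(var_counts) else rep(0,
                                                                length(genes))
  ratio <- n_priv / pmax(mean_var, pseudocount)

  if (null == "permutation") {
    p <- .permutation_pvalues(x, priv_gr, flank_bp, n_priv, nPerm, seed)
  } else {
    rate <- sum(priv) / genomeSize(x)
    if (null == "poisson") {
      lam <- rate * flank_bp
      tail_ge <- stats::ppois(n_priv - 1, lam, lower.tail = FALSE)
      mass <- stats::dpois(n_priv, lam)
    } else {
      tail_ge <- pbinom(n_priv - 1, size = round(flank_bp),
                        prob = min(rate, 1), lower.tail = FALSE)
      mass <- stats::dbinom(n_priv, size = round(flank_bp),
                            prob = min(rate, 1))
    }
    p <- switch(pType,
      exact = tail_ge,
      midp = tail_ge - 0.5 * mass,
      randomized = {
        u <- if (is.null(seed)) stats::runif(length(tail_ge))
             else withr::with_seed(seed, stats::runif(length(tail_ge)))
        tail_ge - u * mass
      })
    p <- pmin(pmax(p, 0), 1)
  }
  p[flank_bp == 0] <- 1
  out <- data.frame(gene_id = genes, flank_bp = flank_bp,
                    n_private_focal = n_priv, mean_variable_other = mean_var,
                    ratio = ratio, p_value = p)
  if (adjust == "BH") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$q_value < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out[order(out$p_value, out$gene_id), , drop = FALSE]
}

## Empirical null: counts of private sites in windows of the same total
## length re-drawn uniformly from the genome (one pool per distinct length).
.permutation_pvalues <- function(x, priv_gr, flank_bp, n_priv, nPerm,
                                 permSeed) {
  si <- GenomeInfoDb::seqinfo(x@sites)
  lens <- as.numeric(GenomeInfoDb::seqlengths(si))
  offs <- cumsum(c(0, lens))[seq_along(lens)]
  names(offs) <- GenomeInfoDb::seqnames(si)
  gpos <- sort(offs[as.character(GenomeInfoDb::seqnames(priv_gr))] +
                 BiocGenerics::start(priv_gr))
  total <- sum(lens)
  draw <- function() {
    p <- numeric(length(flank_bp))
    for (L in unique(flank_bp)) {
      if (L <= 0) next
      ## windows wholly inside one chromosome
      ok_chr <- which(lens >= L)
      wchr <- ok_chr[sample.int(length(ok_chr), nPerm, replace = TRUE,
                                prob = lens[ok_chr] - L + 1)]
      wstart <- offs[wchr] + floor(stats::runif(nPerm) *
                                     (lens[wchr] - L + 1)) + 1
      cnt <- findInterval(wstart + L - 1, gpos) - findInterval(wstart - 1,
                                                               gpos)
      sel <- flank_bp == L
      p[sel] <- vapply(n_priv[sel], function(xx)
        (1 + sum(cnt >= xx)) / (nPerm + 1), numeric(1))
    }
    p
  }
  if (is.null(permSeed)) draw() else withr::with_seed(permSeed, draw())
}

#' Compare private-allele proportions for a gene set across species
#'
#' For each species of the panel, the proportion of private alleles among
#' all variable sites within the gene set's flanking windows: private sites
#' for that species divided by sites variable in any sample of the panel.
#'
#' @param x a [VariantPanel-class].
#' @param flanks GRanges of flank windows from [buildFlankWindows()].
#' @param geneSet character vector of gene ids (must be a subset of the
#'   genes in `flanks`).
#' @param panel a [SpeciesPanel-class] (defaults to the panel of `x`).
#' @return data.frame (species_id, n_private, n_variable, proportion) sorted
#'   by decreasing proportion.
#' @export
compareGeneSet <- function(x, flanks, geneSet, panel = samplePanel(x)) {
  if (!length(geneSet)) stop("geneSet must not be empty")
  absent <- setdiff(geneSet, S4Vectors::mcols(flanks)$gene_id)
  if (length(absent))
    stop("gene(s) not in flank windows: ", paste(absent, collapse = ", "))
  win <- flanks[S4Vectors::mcols(flanks)$gene_id %in% geneSet]
  in_win <- IRanges::overlapsAny(x@sites, win)
  g1 <- x@gt1; g2 <- x@gt2
  variable <- (g1 != g2) | (g1 != 0L) | (g2 != 0L)
  variable[is.na(variable)] <- FALSE
  n_variable <- sum(rowSums(variable) > 0 & in_win)
  species <- unique(panel@samples$species_id)
  n_priv <- vapply(species, function(s)
    sum(isPrivate(x, s, panel) & in_win), numeric(1))
  out <- data.frame(species_id = species, n_private = n_priv,
                    n_variable = n_variable,
                    proportion = if (n_variable > 0) n_priv / n_variable
                                 else rep(NA_real_, length(species)))
  rownames(out) <- NULL
  out[order(-out$proportion, out$species_id), , drop = FALSE]
}
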