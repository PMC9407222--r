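## Independent brute-force re-implementations of every scan statistic, used
## as exact oracles. Deliberately written as plain nested loops over the raw
## genotype arrays - no interval machinery, no cumulative sums.

oracle_window_het <- function(vp, sample, windows) {
  g <- genotypeMatrices(vp)
  a1 <- g$gt1[, sample]; a2 <- g$gt2[, sample]
  chrom <- as.character(seqnames(variantSites(vp)))
  pos <- start(variantSites(vp))
  wchr <- as.character(seqnames(windows))
  ws <- start(windows); we <- end(windows)
  n_het <- n_called <- integer(length(windows))
  for (i in seq_along(windows)) {
    for (j in seq_along(pos)) {
      if (chrom[j] == wchr[i] && pos[j] >= ws[i] && pos[j] <= we[i]) {
        if (!is.na(a1[j])) {
          n_called[i] <- n_called[i] + 1L
          if (a1[j] != a2[j]) n_het[i] <- n_het[i] + 1L
        }
      }
    }
  }
  list(n_het = n_het, n_called = n_called)
}

## pos: sorted site positions of one chromosome; het/miss: logicals
oracle_roh_chrom <- function(pos, het, miss, p) {
  n <- length(pos); w <- p@scanSnpCount
  if (n < w) return(NULL)
  nw <- n - w + 1L
  hit <- logical(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + w - 1L)
    hit[i] <- sum(het[idx]) <= p@maxHetInScan &&
      sum(miss[idx]) <= p@maxMissingInScan
  }
  qual <- logical(n)
  for (j in seq_len(n)) {
    cover <- max(1L, j - w + 1L):min(j, nw)
    qual[j] <- mean(hit[cover]) >= p@hitThreshold
  }
  runs <- list(); cur <- integer(0)
  for (j in seq_len(n)) {
    if (qual[j]) {
      if (length(cur) && pos[j] - pos[cur[length(cur)]] > p@maxGap) {
        runs <- c(runs, list(cur)); cur <- integer(0)
      }
      cur <- c(cur, j)
    } else if (length(cur)) {
      runs <- c(runs, list(cur)); cur <- integer(0)
    }
  }
  if (length(cur)) runs <- c(runs, list(cur))
  out <- NULL
  for (r in runs) {
    span <- pos[r[length(r)]] - pos[r[1]] + 1
    if (length(r) >= p@minSnps && span >= p@minLength)
      out <- rbind(out, data.frame(start = pos[r[1]],
                                   end = pos[r[length(r)]],
                                   n_snps = length(r)))
  }
  out
}

oracle_roh <- function(vp, sample, p) {
  g <- genotypeMatrices(vp)
  a1 <- g$gt1[, sample]; a2 <- g$gt2[, sample]
  chrom <- as.character(seqnames(variantSites(vp)))
  pos <- start(variantSites(vp))
  out <- NULL
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    het <- !is.na(a1[sel]) & a1[sel] != a2[sel]
    miss <- is.na(a1[sel])
    segs <- oracle_roh_chrom(pos[sel], het, miss, p)
    if (!is.null(segs)) out <- rbind(out, cbind(chrom = ch, segs))
  }
  out
}

oracle_private <- function(vp, focal) {
  panel <- samplePanel(vp)
  ids <- sampleIds(panel)
  sp <- setNames(panel@samples$species_id, ids)
  g <- genotypeMatrices(vp)
  mc <- mcols(variantSites(vp))
  vapply(seq_len(nSites(vp)), function(i) {
    alleles <- c(mc$ref[i], mc$alt[[i]])
    anc <- mc$ancestral[i]
    cand <- if (!is.na(anc)) which(alleles != anc) - 1L
            else seq_along(mc$alt[[i]])
    nf_called <- FALSE
    for (s in ids[sp != focal])
      if (!is.na(g$gt1[i, s])) nf_called <- TRUE
    if (!nf_called) return(FALSE)
    for (a in cand) {
      in_focal <- FALSE; in_other <- FALSE
      for (s in ids) {
        if (is.na(g$gt1[i, s])) next
        carries <- g$gt1[i, s] == a || g$gt2[i, s] == a
        if (carries && sp[s] == focal) in_focal <- TRUE
        if (carries && sp[s] != focal) in_other <- TRUE
      }
      if (in_focal && !in_other) return(TRUE)
    }
    FALSE
  }, logical(1))
}

oracle_load <- function(vp, sample) {
  g <- genotypeMatrices(vp)
  mc <- mcols(variantSites(vp))
  hom <- het <- denom <- excl <- 0L
  for (i in seq_len(nSites(vp))) {
    if (is.na(mc$deleterious[i]) || !mc$deleterious[i]) next
    if (is.na(mc$ancestral[i])) { excl <- excl + 1L; next }
    a1 <- g$gt1[i, sample]; a2 <- g$gt2[i, sample]
    if (is.na(a1)) next
    denom <- denom + 1L
    alleles <- c(mc$ref[i], mc$alt[[i]])
    derived <- function(a) {
      aa <- alleles[a + 1L]
      is.na(aa) || aa != mc$ancestral[i]
    }
    if (a1 == a2 && derived(a1)) hom <- hom + 1L
    if (a1 != a2 && (derived(a1) || derived(a2))) het <- het + 1L
  }
  list(hom = hom, het = het, denom = denom, excluded = excl)
}
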