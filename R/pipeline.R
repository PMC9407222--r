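## End-to-end orchestration: heterozygosity -> ROH -> private scan -> load,
## from one YAML config, with a single seed feeding named substreams so each
## stage is independently reproducible.

.default_config <- function() {
  list(window_size = 100000L, window_step = 10000L, flank = 1000L,
       alpha = 0.01, pseudocount = 1, null = "poisson", n_perm = 10000L,
       seed = 1L, excluded_chromosomes = list(), roh = list(),
       impact_key = "IMPACT", del_key = "DEL", gene_key = "GENE",
       aa_key = "AA", focal_species = list())
}

#' Read and validate a pipeline run configuration
#'
#' The YAML must name the input paths (`vcf`, `gff` or `bed`, `panel`,
#' `layout`, optional `mask`) and may override stage parameters:
#' `window_size`, `window_step` (heterozygosity), a `roh` block (see
#' [rohParams()]), `flank`, `alpha`, `pseudocount`, `null`, `n_perm`
#' (private scan), `focal_species`, `excluded_chromosomes`, `seed`, and the
#' annotation INFO keys (`impact_key`, `del_key`, `gene_key`, `aa_key`).
#'
#' @param path YAML file.
#' @return A validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- utils::modifyList(.default_config(), yaml::read_yaml(path))
  for (p in c("vcf", "panel", "layout")) {
    if (is.null(cfg[[p]])) stop("config is missing required path: ", p)
    cfg[[p]] <- .resolve_path(cfg[[p]], dirname(path))
    if (!file.exists(cfg[[p]]))
      stop("config path does not exist: ", p, " = ", cfg[[p]])
  }
  for (p in c("gff", "bed", "mask")) {
    if (!is.null(cfg[[p]])) {
      cfg[[p]] <- .resolve_path(cfg[[p]], dirname(path))
      if (!file.exists(cfg[[p]]))
        stop("config path does not exist: ", p, " = ", cfg[[p]])
    }
  }
  if (cfg$window_step > cfg$window_size)
    stop("window_step must not exceed window_size")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.resolve_path <- function(p, base) {
  if (grepl("^/", p) || file.exists(p)) p else file.path(base, p)
}

.stage_seed <- function(seed, k) (as.integer(seed) * 131L + k) %% 2147483647L

#' Run the complete scan pipeline from a configuration
#'
#' Executes heterozygosity (per-sample window tracks + per-site rates), ROH
#' calling and class summaries, the private-allele flanking-window scan for
#' every focal species, high-impact filtering and damaging load, writing
#' per-stage TSV/BED/BEDGRAPH files and a single JSON summary. Identical
#' config and seed produce byte-identical outputs.
#'
#' @param config path to a YAML config or a list from [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
runAll <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(outDir, "run.log"), "wb")
  on.exit(close(log_con))
  t0 <- proc.time()[["elapsed"]]
  logmsg <- function(...) {
    line <- paste0("[", sprintf("%8.2fs", proc.time()[["elapsed"]] - t0),
                   "] ", ...)
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e),
           " (outputs so far in ", outDir, ")", call. = FALSE))
  }

  layout <- readGenomeLayout(config$layout)
  panel <- readSpeciesPanel(config$panel,
                            focal = unlist(config$focal_species))
  vp <- stage("read", readVariantPanel(config$vcf, panel, layout,
                                       aaKey = config$aa_key,
                                       impactKey = config$impact_key,
                                       delKey = config$del_key,
                                       geneKey = config$gene_key))
  excl <- unlist(config$excluded_chromosomes)
  vpa <- dropChromosomes(vp, excl)
  layout_a <- GenomeInfoDb::seqinfo(variantSites(vpa))
  mask <- if (!is.null(config$mask))
    rtracklayer::import(config$mask, format = "bed") else NULL
  seed <- config$seed

  ## heterozygosity
  summary <- list(seed = seed,
                  version = as.character(utils::packageVersion("comparascan")))
  wins <- tileWindows(layout_a, config$window_size, config$window_step)
  het <- stage("het", {
    per_site <- vapply(sampleIds(vpa), function(s)
      perSiteHeterozygosity(vpa, s), numeric(1))
    for (s in sampleIds(vpa)) {
      tr <- windowHeterozygosity(vpa, s, wins, mask = mask)
      writeWindowTrack(tr, file.path(outDir, paste0("het_", s, ".tsv")),
                       bedgraph = TRUE, seed = seed)
    }
    per_site
  })
  summary$per_site_het_per_kb <- as.list(het)

  ## ROH
  rp <- do.call(rohParams, config$roh)
  roh_tab <- stage("roh", {
    all_segs <- list()
    roh_summary <- list()
    for (s in sampleIds(vpa)) {
      segs <- suppressWarnings(callROH(vpa, s, rp))
      writeROHBed(segs, file.path(outDir, paste0("roh_", s, ".bed")),
                  seed = seed)
      sm <- classifyAndSummarize(segs, layout_a)
      roh_summary[[s]] <- c(
        stats::setNames(as.list(sm$per_class$n_segments),
                        paste0("n_", sm$per_class$class)),
        stats::setNames(as.list(sm$per_class$summed_bp),
                        paste0("bp_", sm$per_class$class)),
        list(froh = sm$froh))
      all_segs[[s]] <- segs
    }
    roh_summary
  })
  summary$roh <- roh_tab

  ## private scan + gene set + load per focal species
  tx_path <- if (!is.null(config$gff)) config$gff else config$bed
  if (!is.null(tx_path)) {
    tx <- longestIsoforms(readTranscripts(tx_path))
    flanks <- buildFlankWindows(tx, flank = config$flank, layout = layout_a)
    scan_res <- stage("scan", {
      res <- list()
      for (i in seq_along(focalSpecies(panel))) {
        f <- focalSpecies(panel)[i]
        sc <- scanGenes(vpa, flanks, f, alpha = config$alpha,
                        pseudocount = config$pseudocount,
                        null = config$null, nPerm = config$n_perm,
                        seed = .stage_seed(seed, i))
        .write_tsv(sc, file.path(outDir, paste0("scan_", f, ".tsv")),
                   seed = seed)
        res[[f]] <- sc$gene_id[sc$significant]
      }
      res
    })
    summary$significant_genes <- scan_res
  }

  load_tab <- stage("load", {
    mc <- S4Vectors::mcols(variantSites(vpa))
    if (any(!is.na(mc$deleterious) & mc$deleterious &
              !is.na(mc$ancestral))) {
      lt <- damagingLoadAll(vpa)
      .write_tsv(lt, file.path(outDir, "load.tsv"), seed = seed)
      lt
    } else NULL
  })
  if (!is.null(load_tab))
    summary$damaging_hom_derived <-
      stats::setNames(as.list(load_tab$n_damaging_hom_derived),
                      load_tab$sample_id)

  hi_tab <- stage("high_impact", {
    mc <- S4Vectors::mcols(variantSites(vpa))
    if (any(!is.na(mc$impact))) {
      res <- list()
      for (f in focalSpecies(panel)) {
        hi <- uniqueHighImpact(vpa, f)
        .write_tsv(hi$variants,
                   file.path(outDir, paste0("high_impact_", f, ".tsv")),
                   seed = seed)
        res[[f]] <- list(n_genes = hi$n_genes, n_variants = hi$n_variants)
      }
      res
    } else NULL
  })
  if (!is.null(hi_tab)) summary$high_impact <- hi_tab

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done")
  invisible(summary)
}
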