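#!/usr/bin/env Rscript
## Model-level oracle for the enrichment-scan power scenario: 2,000 genes with
## 2-kb flank pairs on a 10-Mb genome, background private rate 0.001/bp,
## 10-fold enrichment at 20 target genes. Simulates the generative model
## directly (independent Poisson counts per gene + genome-wide rate
## estimation + one-sided Poisson mid-P test at alpha = 0.01) and records
## robust bounds on recall and false positives. Run once; the resulting
## fixture (tests/testthat/fixtures/power-oracle.json) is frozen and consumed
## by the acceptance tests and script.
set.seed(20260925)
G <- 1e7; n_genes <- 2000; L <- 2000
r <- 0.001; ef <- 10; n_target <- 20
alpha <- 0.01
reps <- 5000
recall <- fp <- integer(reps)
for (i in seq_len(reps)) {
  lam_bg <- r * L
  x <- rpois(n_genes, lam_bg)
  tgt <- seq_len(n_target)
  x[tgt] <- rpois(n_target, ef * lam_bg)
  bg_out <- rpois(1, r * (G - n_genes * L))
  ## rate estimated from all privates incl. enriched genes (as the scan does)
  rate_hat <- (sum(x) + bg_out) / G
  lam_hat <- rate_hat * L
  p <- ppois(x - 1, lam_hat, lower.tail = FALSE) - 0.5 * dpois(x, lam_hat)
  sig <- p < alpha
  recall[i] <- sum(sig[tgt])
  fp[i] <- sum(sig[-tgt])
}
out <- list(
  scenario = "scan_power",
  n_genes = n_genes, n_target = n_target, enrichment_factor = ef,
  background_rate_per_bp = r, flank_pair_bp = L, alpha = alpha,
  oracle_reps = reps,
  recall_mean = mean(recall),
  recall_q01 = as.integer(quantile(recall, 0.01, type = 1)),
  fp_mean = mean(fp),
  fp_q99 = as.integer(quantile(fp, 0.99, type = 1)))
dir.create("tests/testthat/fixtures", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(out, "tests/testthat/fixtures/power-oracle.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
print(out)
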