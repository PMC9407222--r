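# comparascan

Comparative genomic scans for multi-species diploid resequencing panels.

Studies that resequence a clade of related species against one reference
genome — wild canid panels are the motivating case — lean on a small set of
per-sample and per-lineage scan statistics to describe diversity, inbreeding
and lineage-specific change:

* **Sliding-window and per-site heterozygosity.** For sample *i*, window *w*:
  `het/kb = n_het(i, w) / (callable length of w in kb)`, with the genome-wide
  per-site rate as the callable-length-weighted mean. Wild canids span
  roughly 0.3–2 het/kb.
* **Runs of homozygosity (ROH).** A PLINK-style scanning-window caller
  (windows of 50 sites, ≤1 het, ≤5 missing; site hit-fraction threshold 5%;
  runs ≥100 sites, ≥100 kb, gaps ≤1 Mb), with segments classified short
  (0.1–1 Mb), medium (1–10 Mb) or long (≥10 Mb) and summarized as counts,
  summed lengths, genome fractions and `F_ROH = total ROH length / genome
  length`.
* **Private-allele enrichment in regulatory flanks.** For every gene
  (longest isoform), the 1-kb windows flanking the transcript start and end
  are scored for alleles private to a focal lineage versus the mean number
  of variable sites in the remaining species, with a one-sided P value
  against a Poisson null (`expectation = genome-wide private rate × flank
  length`; binomial and permutation nulls available) and the conventional
  raw `P < 0.01` significance call.
* **Lineage-unique high-impact variants and genetic load.** HIGH-impact
  variants private to a focal species grouped by gene, and per-sample counts
  of genotypes homozygous for a derived allele flagged damaging (the
  reference allele is never assumed ancestral).

All of it is driven by a multi-species genotype **simulator** that emits
VCF/GFF3/truth files with exact bookkeeping (implanted autozygous tracts,
injected private alleles with configurable enrichment near target genes,
damaging-allele biases), so every stage has a parameter-recovery test.

Inputs: a multi-sample VCF 4.x (ancestral allele, impact category,
deleterious flag and gene id read from configurable INFO keys), a two-column
chromosome-length TSV, a two-column sample→species TSV, and a GFF3 or BED12
transcript annotation.

## Worked example

`writeDemoInputs()` simulates a three-species toy panel (two bush dogs as the
focal lineage with private alleles enriched near five target genes and a
damaging-allele bias in `bush_dog_1`; an island fox carrying an implanted
1.2-Mb autozygous tract; outbred mainland foxes) and writes every input the
pipeline needs; `runAll()` executes heterozygosity → ROH → scan → load from
the YAML config:

```r
library(comparascan)
cfg <- writeDemoInputs("demo", seed = 1)
res <- runAll(cfg, "demo/out")

round(unlist(res$per_site_het_per_kb), 3)
#>     bush_dog_1     bush_dog_2   island_fox_1   island_fox_2 mainland_fox_1
#>          0.422          0.433          0.281          0.478          1.530
#> mainland_fox_2
#>          1.530

str(res$roh$island_fox_1)
#> List of 7
#>  $ n_short  : int 0
#>  $ n_medium : int 1
#>  $ n_long   : int 0
#>  $ bp_short : num 0
#>  $ bp_medium: num 1201703
#>  $ bp_long  : num 0
#>  $ froh     : num 0.401

res$significant_genes
#> $bush_dog
#> [1] "g00004" "g00003" "g00001" "g00005"

unlist(res$damaging_hom_derived)
#>     bush_dog_1     bush_dog_2   island_fox_1   island_fox_2 mainland_fox_1
#>             82             29              0              0              0
#> mainland_fox_2
#>              0
```

Reading the output: the mainland foxes show the high heterozygosity of a
large outbred population while the focal lineage sits near 0.4 het/kb; the
implanted 1.2-Mb tract in `island_fox_1` is recovered as one medium-class
ROH covering 40% of the toy genome (`froh = 0.401`); four of the five
enriched target genes pass `P < 0.01` in the flanking-window scan; and
`bush_dog_1`, simulated with a doubled homozygous-damaging bias, carries
about twice the damaging homozygote load of its conspecific (82 vs 29).
Per-stage TSV/BED/BEDGRAPH files and `summary.json` land in `demo/out`, and
re-running with the same seed reproduces them byte for byte.

The same stages are available as standalone functions
(`windowHeterozygosity()`, `callROH()`, `scanGenes()`, `damagingLoad()`, …)
and through a thin command-line wrapper, `inst/cli/comparascan.R`.

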