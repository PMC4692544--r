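# tandemAPA

Analysis of alternative polyadenylation (APA) from 3'-end sequencing
reads: poly(A)-site calling, tandem 3'UTR shortening statistics, and
stop-codon isoform-switch detection.

## What it does, and for whom

3'-end sequencing protocols (oligo-d(T)-primed libraries read toward the
poly(A) tail) report one genomic position per transcript: the last
transcribed base before the tail. For anyone comparing APA between two
conditions — tumor vs normal lines, differentiation time points,
stimulated vs resting cells — the downstream analysis is always the same
and rarely packaged: clean internal-priming artifacts against the genome,
cluster read 3'-ends into poly(A) sites per sample, merge and threshold
across samples, normalize depths, map sites onto a stop-codon-keyed gene
set, and then test each gene for a usage shift between conditions.
`tandemAPA` implements that pipeline as composable, tested R functions,
plus a synthetic-data generator with a known truth catalog so every stage
can be validated without external data.

## The statistics at its core

**Standardized 3'UTR length.** For a gene with tandem sites at distances
`l_1 < ... < l_C` from the stop codon, lengths are standardized by the
longest (`ℓ_i = l_i / l_C`, so the distal site scores 1.0) and the
per-sample index is the read-weighted mean `L̄_s = Σ ℓ_i c_is / Σ c_is`.

**Linear-trend test of independence.** Per gene, a 2×C table of counts
(rows: the two groups, scored 0/1; columns: sites proximal→distal, scored
`ℓ_i`) is tested with

```
M² = (n − 1) r²,   M² ~ χ²(1) under independence,
```

where `r` is the Pearson correlation of row and column scores over the
n observations the table represents. `r < 0` means reads sit at shorter
3'UTRs in group B — the gene is *shortened*. P-values are adjusted by
Benjamini–Hochberg FDR across genes.

**Isoform switching.** Gene clusters with distinct stop codons (full vs
truncated protein forms) are tested with a two-sided Fisher exact test on
the 2×2 table of condition-mean expressions (proximal vs distal isoform),
Bonferroni-corrected.

See `vignettes/tandemAPA-methods.Rmd` for assumptions, parameter
defaults, and what the synthetic generator does and does not emulate.

## Worked example

Simulate a two-condition experiment (60 genes, 3 replicates per
condition, 5,000 reads per sample, 10% internal-priming reads) and run
the pipeline:

```r
library(tandemAPA)

cfg   <- sim_config(n_genes = 60, depth_per_sample = 5000, seed = 20)
sim   <- simulate_apa_genome(cfg)
reads <- simulate_reads(sim)
smp   <- sort(unique(reads$sample))
res   <- run_apa_pipeline(reads[, c("chrom", "pos", "strand", "sample")],
                          sim$genome, sim$genes,
                          conditions = setNames(sub("_.*", "", smp), smp))
#> [pipeline] 30240 reads, 6 samples (A: 3, B: 3)
#> [site_calling] kept 27134 / removed 3106 reads; 156 sites pass the 12-read threshold
#> [annotation] categories: 3'UTR=156
#> [tandem] 156 sites on a single 3'UTR; 49 tandem genes
#> [trend] 49 genes tested; 5 shortened, 0 lengthened (q < 0.05)
#> [switch] 0 clusters tested; 0 significant

head(subset(res$trend, significant), 3)
#>     gene_id n_sites   n          r       M2            p            q direction
#> 8  gene0008       3 418 -0.3341286 46.55467 8.909777e-12 2.182895e-10 shortened
#> 18 gene0018       3 431 -0.2963151 37.75514 8.020491e-10 1.310014e-08 shortened
#> 36 gene0042       4 420 -0.2853148 34.10849 5.212324e-09 6.385097e-08 shortened
```

Reading the trend rows: `n` is the table total after depth normalization,
`r < 0` says read mass moved to proximal sites in condition B, `M2` is
the trend statistic, and `mean_len_A`/`mean_len_B` (also in the table)
show the per-condition standardized length index dropping for the called
genes (e.g. 0.72 → 0.51 for gene0008). The generator planted proximal
shifts in 10% of multi-site genes; the five calls above are exactly those
genes.

The single-table primitive is exported too:

```r
linear_trend_test(rbind(A = c(30, 10), B = c(10, 30)), col_scores = c(0.4, 1.0))
#> $r 0.5   $M2 19.75   $n 80   $p 8.83e-06   $direction "lengthened"
```

A thin command-line wrapper with `simulate` and `run` subcommands is in
`inst/scripts/apa_pipeline.R`.

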