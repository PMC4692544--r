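---
title: "Methods: poly(A)-site calling and tandem 3'UTR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-site calling and tandem 3'UTR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemAPA)
```

# The problem

Most mammalian genes carry more than one cleavage-and-polyadenylation site.
When several sites sit in the same 3'UTR ("tandem APA sites"), the gene
produces mRNA isoforms with identical coding sequence but 3'UTRs of
different lengths — and hence different complements of microRNA and
RNA-binding-protein sites. Proliferating and transformed cells tend to
shift usage toward proximal sites, globally shortening 3'UTRs. A second,
rarer class of APA events changes which stop codon is used, truncating the
encoded protein.

3'-end sequencing protocols read out exactly one position per transcript:
the genomic coordinate of the last transcribed base before the poly(A)
tail. `tandemAPA` takes those mapped 3'-end positions (it does not align
reads) and carries them through to poly(A)-site calls, per-gene 3'UTR
length indices, a per-gene test of 3'UTR shortening between two
conditions, and stop-codon isoform-switch calls.

# From read 3'-ends to a site catalog

**Internal-priming filter.** Oligo-d(T) primers anneal to genomically
encoded A-stretches as well as to real poly(A) tails, creating spurious
3'-ends. A read is discarded when the genomic window immediately downstream
of its 3'-end (strand-aware, 10 nt by default) contains a run of ≥ 6
consecutive A or ≥ 7 A in total. Both thresholds are parameters
(`a_run`, `a_window`); the 6-consecutive / 7-of-10 defaults are standard
practice for oligo-d(T) protocols. Windows truncated at a contig edge are
evaluated on the available bases; a read beyond the chromosome end is an
error naming the record.

**Gap clustering.** Within each sample, surviving 3'-end positions are
clustered per (chromosome, strand) by single linkage: sorted positions
start a new cluster whenever the gap to the previous position exceeds
`max_gap` (default 24 nt, a conventional 3'-end clustering window). The
representative cleavage position of a cluster is its modal read position;
ties break toward the 5' end of the transcribed strand so output is
deterministic. Reads on opposite strands never co-cluster.

**Cross-sample merging.** Per-sample representative positions are
re-clustered with the same gap rule; a merged site's position is the
read-count-weighted mode of its members and per-sample raw counts are
carried along. Summed counts are conserved exactly through both steps —
a property the tests assert rather than assume.

**Threshold and normalization.** Sites are kept when their raw counts
summed over all samples reach `min_reads` (default 12; applied to the
cross-sample sum). Counts are then scaled so every sample's total equals
the smallest per-sample total ("scaled to the shallowest sample"), which
makes counts comparable across libraries of different depth without a
model-based normalization.

# Annotation

Genes may share a stop codon across transcript isoforms with different
annotated 3'UTR ends; `build_gene_dataset()` keeps, per distinct
(chromosome, strand, stop codon), the transcript with the largest 3'UTR
(ties resolved toward the more 3'-extending interval). Sites are then
assigned exactly one category by priority: `known_polyA` (within a
tolerance — default 24 nt, deliberately the same constant as the cluster
gap — of a user-supplied known-site catalog) > `3'UTR` > `intron` > `CDS`
> `1kb_downstream` > `noncoding` > `intergenic`. Noncoding and intergenic
are kept separate but can be reported merged. Only sites falling in
exactly one gene's 3'UTR enter the tandem analysis; sites in overlapping
UTRs are ambiguous and dropped.

Two sequence diagnostics support the catalog: `detect_polya_signal()`
scans the upstream window (default −40..−1 nt, covering the A-rich zone
where the signal is expected) for the twelve single-base variants of
AATAAA in fixed priority order (AATAAA, then ATTAAA, then the weak
variants) and reports the first variant found with the occurrence closest
to the cleavage site; `nucleotide_profile()` tabulates strand-aware base
frequencies in a ±50 nt window. On real data these reproduce the
well-known A-rich region at −25..−10 (the signal) and T/U-rich region
near +20 (the CstF binding element).

# The tandem 3'UTR shortening test

For a gene with C ≥ 2 tandem sites, the 3'UTR length of each isoform is
the strand-aware distance from the stop codon to the site. To compare
across genes these lengths are standardized by the gene's longest 3'UTR,
so the distal-most site scores 1.0 and the index

$$\bar{L}_s = \frac{\sum_i \ell_i\, c_{is}}{\sum_i c_{is}} \in (0, 1]$$

(the count-weighted mean standardized length in sample $s$) summarizes the
gene's 3'UTR usage in one number per sample.

Shortening between two groups is tested with a linear-trend test of
independence on the 2×C contingency table of read counts (rows: the two
groups, scored 0 and 1; columns: sites proximal→distal, scored by their
standardized lengths). With $r$ the Pearson correlation of row and column
scores over the n observations the table represents (computed
count-weighted; identical to expanding the table into n scored
observations), the statistic

$$M^2 = (n - 1)\, r^2$$

is asymptotically $\chi^2_1$ under independence. A negative $r$ means read
mass sits at shorter 3'UTRs in the score-1 group: that gene is called
*shortened* in group B. The single degree of freedom against the ordered
alternative gives this test more power than the general C−1 df
independence test when the change is a coherent proximal/distal shift.
$M^2$ is invariant to affine transformations of the column scores (so the
standardization affects interpretability, not p-values) and equals
$(n-1)/n$ times the Cochran–Armitage trend chi-square with the same
scores — both identities are asserted numerically in the tests against
independent implementations.

Counts entering the table are depth-normalized counts rounded to the
nearest integer, since n must be integral for the expanded-observation
definition. Degenerate tables (an empty row, or all reads in one column)
have undefined $r$ and are skipped with a recorded reason rather than
forced. P-values are taken at machine precision with no continuity
correction, and Benjamini–Hochberg FDR is estimated over the tested genes
(`bh_fdr()`, the standard step-up procedure).

Comparisons can run *pooled* (replicates of each condition summed — the
default) or *pairwise* (every replicate-of-A × replicate-of-B pair, with a
per-gene summary of how many pairs call each direction), mirroring how
replicated designs are typically reported.

# Stop-codon isoform switching

Gene clusters whose members end at different stop codons encode full and
truncated protein forms. Per isoform, expression is the sum of its 3'UTR
sites' normalized counts; per condition, the mean over replicates. The
2×2 table (conditions × proximal/distal isoform; clusters with more than
two isoforms are collapsed to most-proximal vs the rest, a 2×K chi-square
being the obvious generalization) is tested with a two-sided Fisher exact
test, Bonferroni-corrected across clusters. Means are rounded to integers
because the exact test requires counts. The preferred isoform in
condition B is reported only for significant clusters, by comparing
proximal shares between the rows.

# The synthetic-data generator

Real 3'-end datasets at the scale this analysis is designed for are tens
of millions of reads against a full genome annotation; the generator
emulates the *statistical structure* the analysis assumes at desk scale so
every stage can be tested against a known truth:

- one chromosome per gene (no overlap bookkeeping), strand drawn 50/50 to
  exercise strand handling; 200 nt 5' pad, 300 nt CDS, a 3'UTR of
  300–2000 nt, 1100 nt 3' pad;
- 1–4 tandem sites per 3'UTR with pairwise spacing ≥ 80 nt — chosen so
  that cleavage jitter (truncated at ±3 sd = ±15 nt at the default
  sd 5 nt) can never bridge the 24-nt cluster gap between distinct true
  sites, keeping truth matching well-defined;
- AATAAA planted at −21..−16 of every true site and an 8-nt T-run at
  +17..+24 (the CstF-element analog); background sequence i.i.d. uniform,
  rejection-resampled so no accidental AATAAA sits within −40..−1 of a
  true site — signal-detection tests are therefore unambiguous;
- one 10-nt A-run ("trap") per 3'UTR, ≥ 80 nt from any site; internal
  priming emits reads whose 3'-end is the base immediately 5' of the run,
  so the filter's downstream window is pure A;
- per-gene site-usage proportions Dirichlet(3) with a 0.05 floor (a site
  used below 5% is not meaningfully tandem at these depths); a configured
  fraction of multi-site genes gets `effect_size` usage probability moved
  onto the proximal site in condition B;
- per-sample depth Poisson around `depth_per_sample`; genes weighted
  equally (the analysis is driven by within-gene proportions and sample
  depth, which the generator varies; between-gene expression dispersion
  is deliberately not modeled);
- cleavage jitter: discretized Gaussian truncated at ±3 sd, default
  sd 5 nt. The dispersion of real cleavage positions is not well
  characterized; 5 nt is a free-parameter default of this package.

What passing tests on this generator do **not** show: robustness to
overlapping genes and shared UTRs, to non-uniform genomic base
composition (real A-rich 3'UTRs make internal-priming filtering harder
than uniform background does), to alignment and multimapping artifacts,
or to biological covariation between expression level and APA. The
generator is a correctness instrument, not a realism benchmark.

Two count-level companions skip the genome: `simulate_tandem_counts()`
(multinomial site counts with standardized lengths, for calibrating the
trend test on thousands of genes) and `simulate_switch_clusters()`
(proximal/distal isoform counts with planted switches of random
direction).

# Calibration and standard problem sizes

The package's statistical checks run at sizes chosen to make Monte-Carlo
error small relative to the properties asserted: the trend statistic is
compared with a brute-force expanded-observation oracle on 1,000 random
2×C tables (agreement to 1e−10); type-I error is measured on 2,000 null
tandem genes at ~200 reads per gene (rejection at p < 0.05 calibrated to
0.05 ± 0.01); FDR, sensitivity and direction accuracy on 1,000 genes with
10% planted proximal shifts of 0.3; site recovery and artifact removal on
the full simulator at its defaults (100 genes, 10,000 reads per sample,
six samples, 10% internal-priming reads). All of these are recomputed by
`scripts/acceptance.R` at run time from a caller-supplied seed.

# Known limitations

- The gap value behind published 3'-end clusterings varies by protocol;
  24 nt is a convention, not a measurement, and is exposed everywhere it
  is used.
- The 12-read site threshold is applied to the cross-sample sum; applying
  it per sample is stricter and would be a one-line change.
- The trend test's χ²₁ reference is asymptotic; for genes with very few
  reads the test is slightly liberal. At ≥ 100 reads per row the measured
  type-I error is within a point of nominal.
- Fisher tests on rounded replicate means (rather than a replicate-aware
  model) understate between-replicate variance; corrected p-values should
  be read as ranking evidence for switching, as is usual for this style
  of analysis.
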