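#' Configuration for the synthetic APA data generator
#'
#' Bundles and validates every tunable of the simulator: gene-set size, the
#' distribution of tandem poly(A) sites per 3'UTR, cleavage-position jitter,
#' sequencing depth, replication, and the planted between-condition effect.
#'
#' The defaults describe the scenario the package's own calibration and
#' recovery checks run under: 3 replicates per condition (two conditions,
#' labelled `A` and `B`), 10,000 expected reads per sample, cleavage jitter
#' with a 5-nt standard deviation, 10% of reads emitted at genomic A-rich
#' internal-priming traps, and 10% of multi-site genes with a 0.3 shift of
#' usage probability toward the proximal site in condition `B`.
#'
#' @param n_genes Number of genes; one chromosome is generated per gene.
#' @param sites_per_gene Named numeric vector of probabilities over 1..4
#'   tandem sites per 3'UTR.
#' @param utr_length_range Length-2 integer vector, range (nt) from which
#'   3'UTR lengths are drawn uniformly. Lengths are raised where needed so
#'   that the requested number of sites fits at the minimum spacing.
#' @param cleavage_jitter_sd Standard deviation (nt) of the discretized
#'   Gaussian cleavage jitter, truncated at +/- 3 sd.
#' @param depth_per_sample Expected number of reads per sample (Poisson).
#' @param n_replicates Biological replicates per condition.
#' @param shortening_fraction Proportion of multi-site genes given a
#'   condition effect (proximal shift in condition B).
#' @param effect_size Increase of proximal-site usage probability in
#'   condition B for affected genes (capped so it stays below 0.95).
#' @param internal_priming_rate Proportion of reads emitted at A-rich trap
#'   loci rather than true poly(A) sites.
#' @param min_site_spacing Minimum distance (nt) between tandem sites of one
#'   gene. Must exceed the clustering gap plus twice the jitter truncation
#'   bound so that distinct true sites cannot merge into one read cluster.
#' @param min_utr_offset Minimum distance (nt) from the stop codon to the
#'   most proximal site.
#' @param seed Integer seed; fixes every random draw of the generator.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 7)
#' cfg$depth_per_sample
#' @export
sim_config <- function(n_genes = 100L,
                       sites_per_gene = c("1" = 0.25, "2" = 0.35,
                                          "3" = 0.25, "4" = 0.15),
                       utr_length_range = c(300L, 2000L),
                       cleavage_jitter_sd = 5,
                       depth_per_sample = 10000L,
                       n_replicates = 3L,
                       shortening_fraction = 0.1,
                       effect_size = 0.3,
                       internal_priming_rate = 0.1,
                       min_site_spacing = 80L,
                       min_utr_offset = 100L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sites_per_gene = sites_per_gene,
              utr_length_range = as.integer(utr_length_range),
              cleavage_jitter_sd = cleavage_jitter_sd,
              depth_per_sample = depth_per_sample,
              n_replicates = as.integer(n_replicates),
              shortening_fraction = shortening_fraction,
              effect_size = effect_size,
              internal_priming_rate = internal_priming_rate,
              min_site_spacing = as.integer(min_site_spacing),
              min_utr_offset = as.integer(min_utr_offset),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_genes) || cfg$n_genes < 0L)
    .stopf("n_genes must be a non-negative integer")
  p <- cfg$sites_per_gene
  if (length(p) < 1L || length(p) > 4L || any(p < 0) || sum(p) <= 0)
    .stopf("sites_per_gene must be non-negative probabilities over 1..4 sites")
  if (is.null(names(p)) || !all(names(p) %in% as.character(1:4)))
    .stopf("sites_per_gene must be named with site counts in 1..4")
  if (length(cfg$utr_length_range) != 2L || any(cfg$utr_length_range <= 0) ||
      diff(cfg$utr_length_range) < 0)
    .stopf("utr_length_range must be a positive, non-decreasing interval")
  if (cfg$cleavage_jitter_sd < 0) .stopf("cleavage_jitter_sd must be >= 0")
  if (cfg$depth_per_sample < 0) .stopf("depth_per_sample must be >= 0")
  if (cfg$n_replicates < 1L) .stopf("n_replicates must be >= 1")
  for (fld in c("shortening_fraction", "effect_size", "internal_priming_rate")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      .stopf("%s must lie in [0, 1]", fld)
  }
  if (cfg$min_site_spacing < 1L) .stopf("min_site_spacing must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      2L * x$n_replicates, "samples,",
      "depth", x$depth_per_sample, "per sample\n")
  cat("  sites/gene probs:",
      paste(names(x$sites_per_gene), round(x$sites_per_gene, 3),
            sep = ":", collapse = " "), "\n")
  cat("  jitter sd:", x$cleavage_jitter_sd,
      " priming rate:", x$internal_priming_rate,
      " shortened fraction:", x$shortening_fraction,
      " effect:", x$effect_size, "\n")
  invisible(x)
}

# Sample labels: condition A (baseline) and B (proximal-shifted), numbered
# replicates.
sim_sample_names <- function(cfg) {
  as.vector(vapply(c("A", "B"), function(cond)
    paste0(cond, "_", seq_len(cfg$n_replicates)), character(cfg$n_replicates)))
}
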