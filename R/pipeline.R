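# End-to-end orchestration: simulate a dataset to disk, or run reads ->
# site catalog -> annotation -> tandem trend -> isoform switch, with a
# machine-readable summary.

#' Default pipeline parameters
#'
#' @param max_gap Read-clustering gap (nt), also the known-site matching
#'   tolerance.
#' @param a_run,a_window Internal-priming filter thresholds
#'   ([filter_internal_priming()]).
#' @param min_reads Cross-sample summed read threshold per site.
#' @param signal_window Upstream poly(A)-signal search window.
#' @param flank Nucleotide-profile half-width (nt).
#' @param fdr_alpha BH FDR threshold for trend calls.
#' @param bonferroni_alpha Bonferroni-corrected threshold for switch calls.
#' @param compare `"pooled"` (pooled replicate counts per condition) or
#'   `"pairwise"` (every replicate pair, with an overlap summary).
#' @return Named list of parameters.
#' @export
apa_params <- function(max_gap = 24L, a_run = 6L, a_window = c(7L, 10L),
                       min_reads = 12L, signal_window = c(-40L, -1L),
                       flank = 50L, fdr_alpha = 0.05,
                       bonferroni_alpha = 0.05,
                       compare = c("pooled", "pairwise")) {
  list(max_gap = max_gap, a_run = a_run, a_window = a_window,
       min_reads = min_reads, signal_window = signal_window, flank = flank,
       fdr_alpha = fdr_alpha, bonferroni_alpha = bonferroni_alpha,
       compare = match.arg(compare))
}

#' Run the full APA analysis pipeline
#'
#' Filters internal-priming reads against the genome, clusters each
#' sample's 3'-ends, merges sites across samples, applies the read
#' threshold, normalizes to the shallowest sample, annotates sites,
#' computes signal and composition profiles, tests tandem genes for 3'UTR
#' shortening between the two conditions, and tests stop-codon isoform
#' clusters for switching.
#'
#' @param reads data.frame of read 3'-ends (`chrom`, `pos`, `strand`,
#'   `sample`).
#' @param genome `DNAStringSet`.
#' @param genes Transcript/gene models (passed through
#'   [build_gene_dataset()]).
#' @param conditions Named character vector mapping each sample label to
#'   one of two condition labels; the first level (sorted) is group A.
#' @param known_sites Optional known poly(A)-site data.frame.
#' @param params Parameter list from [apa_params()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there along with `summary.json`.
#' @return List of class `apa_result`: `catalog`, `annotations`, `signal`,
#'   `composition`, `profiles`, `mean_lengths`, `trend` (and `trend_pairs`
#'   in pairwise mode), `switch`, `summary`, `params`.
#' @export
run_apa_pipeline <- function(reads, genome, genes, conditions,
                             known_sites = NULL, params = apa_params(),
                             out_dir = NULL) {
  stopifnot(is.data.frame(reads), !is.null(names(conditions)))
  lvl <- sort(unique(unname(conditions)))
  if (length(lvl) != 2L)
    .stopf("conditions must have exactly 2 levels, got: %s",
           paste(lvl, collapse = ", "))
  samples_a <- names(conditions)[conditions == lvl[1]]
  samples_b <- names(conditions)[conditions == lvl[2]]
  message(sprintf("[pipeline] %d reads, %d samples (%s: %d, %s: %d)",
                  nrow(reads), length(conditions), lvl[1], length(samples_a),
                  lvl[2], length(samples_b)))

  gene_set <- build_gene_dataset(genes)

  if (nrow(reads) == 0L) {
    .warnf("empty read set: producing empty results")
    cs <- list(catalog = merge_sites_across_samples(
      stats::setNames(rep(list(cluster_sample_sites(reads)), length(conditions)),
                      names(conditions)), params$max_gap),
      kept = reads, removed = reads)
  } else {
    cs <- call_sites(reads, genome, max_gap = params$max_gap,
                     min_reads = params$min_reads, a_run = params$a_run,
                     a_window = params$a_window)
  }
  catalog <- cs$catalog
  message(sprintf("[site_calling] kept %d / removed %d reads; %d sites pass the %d-read threshold",
                  nrow(cs$kept), nrow(cs$removed), nrow(catalog),
                  params$min_reads))

  ann <- assign_sites(catalog, gene_set, known_sites = known_sites,
                      tolerance = params$max_gap)
  message(sprintf("[annotation] categories: %s",
                  paste(names(table(ann$category)), table(ann$category),
                        sep = "=", collapse = ", ")))
  signal <- detect_polya_signal(genome, catalog, window = params$signal_window)
  composition <- nucleotide_profile(genome, catalog, flank = params$flank)

  single <- select_single_utr_sites(catalog, ann)
  profiles <- build_tandem_profiles(single, gene_set)
  message(sprintf("[tandem] %d sites on a single 3'UTR; %d tandem genes",
                  nrow(single), length(profiles)))

  trend_pairs <- NULL
  if (params$compare == "pairwise" && length(profiles) > 0L) {
    pw <- apa_trend_pairwise(profiles, samples_a, samples_b,
                             alpha = params$fdr_alpha)
    trend <- pw$pooled
    trend_pairs <- pw
  } else {
    trend <- apa_trend_test(profiles, samples_a, samples_b,
                            alpha = params$fdr_alpha)
  }
  n_short <- sum(trend$significant & trend$direction == "shortened",
                 na.rm = TRUE)
  n_long <- sum(trend$significant & trend$direction == "lengthened",
                na.rm = TRUE)
  message(sprintf("[trend] %d genes tested; %d shortened, %d lengthened (q < %g)",
                  sum(!is.na(trend$p)), n_short, n_long, params$fdr_alpha))

  clusters <- make_isoform_clusters(single, gene_set)
  switch_res <- apa_switch_test(clusters, samples_a, samples_b,
                                alpha = params$bonferroni_alpha)
  message(sprintf("[switch] %d clusters tested; %d significant",
                  nrow(switch_res), sum(switch_res$significant)))

  mean_len <- mean_length_matrix(profiles)
  summary <- list(
    n_reads_in = nrow(reads),
    n_reads_kept = nrow(cs$kept),
    n_reads_removed = nrow(cs$removed),
    n_sites = nrow(catalog),
    categories = as.list(table(ann$category)),
    n_single_utr_sites = nrow(single),
    n_tandem_genes = length(profiles),
    n_trend_tested = sum(!is.na(trend$p)),
    n_shortened = n_short,
    n_lengthened = n_long,
    n_clusters_tested = nrow(switch_res),
    n_switch_significant = sum(switch_res$significant),
    conditions = as.list(conditions))

  res <- structure(list(catalog = catalog, annotations = ann, signal = signal,
                        composition = composition, profiles = profiles,
                        mean_lengths = mean_len, trend = trend,
                        trend_pairs = trend_pairs, switch = switch_res,
                        summary = summary, params = params),
                   class = "apa_result")
  if (!is.null(out_dir)) write_apa_result(res, out_dir)
  res
}

#' @export
print.apa_result <- function(x, ...) {
  s <- x$summary
  cat("apa_result:", s$n_sites, "poly(A) sites,", s$n_tandem_genes,
      "tandem genes,", s$n_shortened, "shortened /", s$n_lengthened,
      "lengthened,", s$n_switch_significant, "switch clusters\n")
  invisible(x)
}

#' Write an `apa_result` bundle to disk
#'
#' Emits one TSV per stage plus `summary.json` (which also echoes the
#' parameters used, for provenance).
#'
#' @param res `apa_result` from [run_apa_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @export
write_apa_result <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv(res$catalog, file.path(out_dir, "site_catalog.tsv"))
  write_tsv(res$annotations, file.path(out_dir, "site_annotation.tsv"))
  write_tsv(res$signal, file.path(out_dir, "polya_signal.tsv"))
  comp <- data.frame(offset = rownames(res$composition), res$composition,
                     check.names = FALSE)
  write_tsv(comp, file.path(out_dir, "nucleotide_composition.tsv"))
  if (length(res$mean_lengths) > 0L) {
    ml <- data.frame(gene_id = rownames(res$mean_lengths), res$mean_lengths,
                     check.names = FALSE)
    write_tsv(ml, file.path(out_dir, "gene_mean_lengths.tsv"))
  }
  write_tsv(res$trend, file.path(out_dir, "trend_results.tsv"))
  write_tsv(res$switch, file.path(out_dir, "switch_results.tsv"))
  jsonlite::write_json(c(res$summary, list(params = res$params)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a complete dataset to disk
#'
#' Runs the generator and writes the genome FASTA, one BED6 file of read
#' 3'-ends per sample, the gene-model table and the truth catalog TSVs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list with the `apa_sim`, the reads and the file
#'   paths.
#' @export
simulate_apa_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_apa_genome(config)
  reads <- simulate_reads(sim, config)
  paths <- list(
    genome = write_genome_fasta(sim$genome, file.path(dir, "genome.fa")),
    genes = write_gene_models(sim$genes, file.path(dir, "gene_models.tsv")),
    reads = write_reads_bed(reads, dir),
    truth_sites = write_tsv(sim$truth$sites, file.path(dir, "truth_sites.tsv")),
    truth_traps = write_tsv(sim$truth$traps, file.path(dir, "truth_traps.tsv")),
    truth_genes = write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv")))
  invisible(list(sim = sim, reads = reads, paths = paths))
}

#' Compare a called site catalog against the simulation truth
#'
#' A true site counts as recovered when a called site on the same
#' chromosome and strand lies within `tol` nt of its cleavage position.
#'
#' @param catalog Called site catalog.
#' @param truth_sites Truth-site table (`chrom`, `strand`, `pos`).
#' @param tol Matching tolerance (nt).
#' @return List: `n_true`, `n_recovered`, `recovery` (fraction), and the
#'   per-site logical `recovered`.
#' @export
evaluate_site_recovery <- function(catalog, truth_sites, tol = 24L) {
  n_true <- nrow(truth_sites)
  if (n_true == 0L)
    return(list(n_true = 0L, n_recovered = 0L, recovery = NA_real_,
                recovered = logical(0)))
  recovered <- vapply(seq_len(n_true), function(i) {
    hit <- catalog$chrom == truth_sites$chrom[i] &
      catalog$strand == truth_sites$strand[i] &
      abs(catalog$rep_pos - truth_sites$pos[i]) <= tol
    any(hit)
  }, logical(1))
  list(n_true = n_true, n_recovered = sum(recovered),
       recovery = mean(recovered), recovered = recovered)
}
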