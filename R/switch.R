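# Stop-codon isoform switching between two conditions: gene clusters whose
# member genes end at different stop codons (truncated-protein isoforms),
# compared with a Fisher exact test on proximal vs distal isoform usage.

#' Build stop-codon isoform clusters from annotated sites
#'
#' Groups gene records by `cluster_id`; clusters whose member genes have
#' two or more distinct stop codons represent truncated-protein isoform
#' families. Per-isoform expression is the sum of the normalized counts of
#' the sites mapped to that isoform's 3'UTR. Isoforms are ordered by
#' stop-codon position along the transcribed strand; clusters with more
#' than two isoforms are collapsed to (most proximal) vs (all distal).
#'
#' @param sites Site catalog subset from [select_single_utr_sites()] (with
#'   `gene_id` and per-sample count columns).
#' @param genes Gene dataset with `cluster_id` and `stop_codon_pos`.
#' @param use_norm Use normalized counts when present.
#' @return Named list of class `isoform_clusters`; each element holds
#'   `cluster_id`, `isoforms` (gene ids, proximal first) and `counts`
#'   (2 x samples matrix, rows `proximal`, `distal`). Clusters with all
#'   zero counts are dropped.
#' @export
make_isoform_clusters <- function(sites, genes, use_norm = TRUE) {
  stopifnot("cluster_id" %in% names(genes), "gene_id" %in% names(sites))
  cols <- if (use_norm && length(.norm_cols(sites)) > 0L)
    .norm_cols(sites) else .raw_cols(sites)
  if (length(cols) == 0L) .stopf("sites carry no per-sample count columns")
  samples <- sub("^(norm|reads)\\.", "", cols)

  out <- lapply(split(genes, genes$cluster_id), function(gm) {
    if (length(unique(gm$stop_codon_pos)) < 2L) return(NULL)
    # order isoforms by stop codon along the transcribed strand
    ord <- if (gm$strand[1] == "+") order(gm$stop_codon_pos)
           else order(-gm$stop_codon_pos)
    gm <- gm[ord, , drop = FALSE]
    expr <- t(vapply(gm$gene_id, function(g) {
      d <- sites[sites$gene_id == g, cols, drop = FALSE]
      if (nrow(d) == 0L) stats::setNames(numeric(length(cols)), cols)
      else colSums(d)
    }, numeric(length(cols))))
    colnames(expr) <- samples
    if (sum(expr) == 0) return(NULL)
    counts <- rbind(proximal = expr[1, ],
                    distal = colSums(expr[-1, , drop = FALSE]))
    structure(list(cluster_id = gm$cluster_id[1], isoforms = gm$gene_id,
                   counts = counts),
              class = "isoform_cluster")
  })
  out <- out[!vapply(out, is.null, TRUE)]
  structure(out, class = "isoform_clusters")
}

#' Per-isoform condition-mean expression of one cluster
#'
#' Sums site counts per isoform per sample (done in
#' [make_isoform_clusters()]) and averages over each condition's
#' replicates.
#'
#' @param cluster An `isoform_cluster`.
#' @param samples_a,samples_b Sample labels of conditions A and B.
#' @return 2 x 2 numeric matrix: rows `A`, `B` (conditions), columns
#'   `proximal`, `distal` (mean expression).
#' @export
isoform_expression <- function(cluster, samples_a, samples_b) {
  stopifnot(inherits(cluster, "isoform_cluster"))
  m <- rbind(A = rowMeans(cluster$counts[, samples_a, drop = FALSE]),
             B = rowMeans(cluster$counts[, samples_b, drop = FALSE]))
  colnames(m) <- c("proximal", "distal")
  m
}

#' Fisher exact test for an isoform switch
#'
#' Two-sided Fisher exact test on the 2 x 2 table of rounded mean isoform
#' expressions (rows: conditions, columns: proximal/distal isoform), with
#' Bonferroni correction over the `m` clusters tested. The preferred
#' isoform in condition B is reported when the corrected p-value passes
#' `alpha`: `proximal` if B's proximal share exceeds A's, else `distal`.
#'
#' @param tab 2 x 2 matrix of non-negative counts (rows `A`, `B`; columns
#'   `proximal`, `distal`). Non-integer values are rounded.
#' @param m Number of clusters tested (Bonferroni factor).
#' @param alpha Significance level on the corrected p-value.
#' @return List: `table`, `odds_ratio` (conditional MLE), `p`, `p_bonf`,
#'   `preference` (`NA` unless `p_bonf <= alpha` and a direction exists).
#' @examples
#' fisher_switch_test(rbind(A = c(10, 0), B = c(0, 10)), m = 1)
#' @export
fisher_switch_test <- function(tab, m = 1L, alpha = 0.05) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0), m >= 1L)
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p = 1,
                p_bonf = 1, preference = NA_character_))
  }
  ft <- stats::fisher.test(tab)
  p_bonf <- min(1, ft$p.value * m)
  share_a <- tab[1, 1] / sum(tab[1, ])
  share_b <- tab[2, 1] / sum(tab[2, ])
  pref <- if (p_bonf <= alpha && share_b != share_a) {
    if (share_b > share_a) "proximal" else "distal"
  } else NA_character_
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       p_bonf = p_bonf, preference = pref)
}

#' Test all isoform clusters for switching between two conditions
#'
#' @param clusters An `isoform_clusters` list.
#' @param samples_a,samples_b Sample labels of the two conditions.
#' @param alpha Significance level on the Bonferroni-corrected p-value.
#' @return data.frame per cluster: counts, odds ratio, `p`, `p_bonf`,
#'   `preference` (preferred stop-codon isoform in condition B when
#'   significant), `significant`.
#' @export
apa_switch_test <- function(clusters, samples_a, samples_b, alpha = 0.05) {
  m <- length(clusters)
  rows <- lapply(clusters, function(cl) {
    expr <- isoform_expression(cl, samples_a, samples_b)
    res <- fisher_switch_test(expr, m = m, alpha = alpha)
    data.frame(cluster_id = cl$cluster_id,
               n_isoforms = length(cl$isoforms),
               A_proximal = res$table[1, 1], A_distal = res$table[1, 2],
               B_proximal = res$table[2, 1], B_distal = res$table[2, 2],
               odds_ratio = res$odds_ratio, p = res$p, p_bonf = res$p_bonf,
               preference = res$preference,
               significant = res$p_bonf <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cluster_id = character(0), n_isoforms = integer(0),
                      A_proximal = numeric(0), A_distal = numeric(0),
                      B_proximal = numeric(0), B_distal = numeric(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      p_bonf = numeric(0), preference = character(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
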