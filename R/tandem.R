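# Per-gene tandem 3'UTR quantification and the linear-trend test of
# independence for between-condition 3'UTR shortening.

#' Build per-gene tandem APA profiles
#'
#' Sites assigned to exactly one 3'UTR are grouped by gene; genes with two
#' or more sites form a tandem profile: sites ordered proximal to distal by
#' their strand-aware distance from the stop codon, each distance divided
#' by the gene's largest so the distal-most site scores 1.0.
#'
#' @param sites Site catalog subset from [select_single_utr_sites()] (must
#'   carry `gene_id` and per-sample count columns).
#' @param genes Gene dataset from [build_gene_dataset()].
#' @param use_norm Use normalized (`norm.<sample>`) counts when present,
#'   falling back to raw counts otherwise.
#' @return A named list of class `tandem_profiles`; each element is a
#'   `tandem_profile` with `gene_id`, `site_id`, `rep_pos`, `utr_len`
#'   (nt from the stop codon), `std_len` (in (0,1], distal-most = 1) and
#'   `counts` (matrix, sites x samples).
#' @export
build_tandem_profiles <- function(sites, genes, use_norm = TRUE) {
  stopifnot("gene_id" %in% names(sites))
  cols <- if (use_norm && length(.norm_cols(sites)) > 0L)
    .norm_cols(sites) else .raw_cols(sites)
  if (length(cols) == 0L) .stopf("sites carry no per-sample count columns")
  gm <- genes[match(sites$gene_id, genes$gene_id), , drop = FALSE]
  utr_len <- ifelse(gm$strand == "+",
                    sites$rep_pos - gm$stop_codon_pos,
                    gm$stop_codon_pos - sites$rep_pos)
  if (any(utr_len <= 0, na.rm = TRUE)) {
    bad <- which(utr_len <= 0)[1]
    .stopf("site %s lies at or upstream of the stop codon of %s",
           sites$site_id[bad], sites$gene_id[bad])
  }
  sites$.utr_len <- utr_len

  profs <- lapply(split(seq_len(nrow(sites)), sites$gene_id), function(i) {
    if (length(i) < 2L) return(NULL)
    d <- sites[i, , drop = FALSE]
    d <- d[order(d$.utr_len), , drop = FALSE]
    cnt <- as.matrix(d[, cols, drop = FALSE])
    colnames(cnt) <- sub("^(norm|reads)\\.", "", cols)
    rownames(cnt) <- NULL
    structure(list(gene_id = d$gene_id[1], chrom = d$chrom[1],
                   strand = d$strand[1], site_id = d$site_id,
                   rep_pos = d$rep_pos, utr_len = d$.utr_len,
                   std_len = d$.utr_len / max(d$.utr_len),
                   counts = cnt),
              class = "tandem_profile")
  })
  profs <- profs[!vapply(profs, is.null, TRUE)]
  structure(profs, class = "tandem_profiles")
}

#' @export
print.tandem_profiles <- function(x, ...) {
  cat("tandem_profiles:", length(x), "genes with >= 2 tandem poly(A) sites\n")
  invisible(x)
}

#' Standardized mean 3'UTR length of one gene in one sample
#'
#' The read-count-weighted mean of the gene's standardized site lengths:
#' sum(std_len * count) / sum(count) over the gene's tandem sites. Returns
#' `NA` when the sample has no reads on the gene.
#'
#' @param profile A `tandem_profile`.
#' @param sample Sample label (a column of the profile's count matrix).
#' @return Value in (0, 1], or `NA` for a zero-count sample.
#' @export
standardized_mean_length <- function(profile, sample) {
  stopifnot(inherits(profile, "tandem_profile"))
  w <- profile$counts[, sample]
  tot <- sum(w)
  if (tot == 0) return(NA_real_)
  sum(profile$std_len * w) / tot
}

#' Standardized mean 3'UTR length for all genes and samples
#'
#' @param profiles A `tandem_profiles` list.
#' @return Numeric matrix, genes x samples, of weighted mean standardized
#'   lengths (`NA` where a sample has no reads on a gene).
#' @export
mean_length_matrix <- function(profiles) {
  if (length(profiles) == 0L) return(matrix(numeric(0), 0, 0))
  samples <- colnames(profiles[[1]]$counts)
  m <- t(vapply(profiles, function(p)
    vapply(samples, function(s) standardized_mean_length(p, s), numeric(1)),
    numeric(length(samples))))
  rownames(m) <- vapply(profiles, `[[`, character(1), "gene_id")
  m
}

#' Construct the 2xC trend table for one gene
#'
#' Rows are the two compared groups (row scores 0 and 1), columns the
#' gene's tandem sites ordered proximal to distal, column scores the
#' standardized 3'UTR lengths. Counts are summed over the samples of each
#' group and rounded to the nearest integer (counts entering the test must
#' be integral).
#'
#' @param profile A `tandem_profile`.
#' @param samples_a,samples_b Sample labels forming rows A (score 0) and B
#'   (score 1).
#' @return List with `table` (2 x C integer matrix, rows `A`, `B`),
#'   `col_scores`, and `ok` (`FALSE` with a `reason` when a row has zero
#'   total).
#' @export
trend_table <- function(profile, samples_a, samples_b) {
  stopifnot(inherits(profile, "tandem_profile"))
  a <- round(rowSums(profile$counts[, samples_a, drop = FALSE]))
  b <- round(rowSums(profile$counts[, samples_b, drop = FALSE]))
  tab <- rbind(A = a, B = b)
  colnames(tab) <- profile$site_id
  if (sum(a) == 0 || sum(b) == 0)
    return(list(table = tab, col_scores = profile$std_len, ok = FALSE,
                reason = "a row has zero total"))
  list(table = tab, col_scores = profile$std_len, ok = TRUE, reason = NA)
}

#' Linear-trend test of independence on a scored 2xC table
#'
#' Tests independence against an ordered alternative. With row scores
#' (0, 1) and the standardized 3'UTR lengths as column scores, the Pearson
#' correlation r of row and column scores is computed over the n
#' observations the table represents (count-weighted), and the statistic
#' M2 = (n - 1) r^2 is referred to a chi-square distribution with one
#' degree of freedom. A negative r means read mass sits at shorter 3'UTRs
#' in the row-score-1 group (shortening in B).
#'
#' @param tab 2 x C matrix of non-negative counts (rows: groups A, B).
#' @param col_scores Numeric column scores, typically standardized 3'UTR
#'   lengths, ordered with the columns.
#' @param row_scores Row scores, default `c(0, 1)`.
#' @return List: `r`, `M2`, `n`, `p` (upper-tail chi-square, df = 1),
#'   `direction` (`"shortened"`/`"lengthened"` in the B row), `ok`,
#'   `reason`. Degenerate tables (all reads in one column, or an empty
#'   row) return `ok = FALSE` with `r` undefined.
#' @examples
#' linear_trend_test(rbind(A = c(30, 10), B = c(10, 30)),
#'                   col_scores = c(0.4, 1.0))
#' @export
linear_trend_test <- function(tab, col_scores, row_scores = c(0, 1)) {
  stopifnot(is.matrix(tab), nrow(tab) == 2L, ncol(tab) == length(col_scores),
            length(row_scores) == 2L, all(tab >= 0))
  n <- sum(tab)
  bad <- function(reason) list(r = NA_real_, M2 = NA_real_, n = n,
                               p = NA_real_, direction = NA_character_,
                               ok = FALSE, reason = reason)
  if (n < 2) return(bad("fewer than 2 observations"))
  w <- as.vector(tab)
  x <- rep(row_scores, times = ncol(tab))
  y <- rep(col_scores, each = 2L)
  mx <- sum(w * x) / n
  my <- sum(w * y) / n
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx == 0) return(bad("a row has zero total"))
  if (syy == 0) return(bad("no column-score variance (all reads in one column)"))
  r <- sum(w * (x - mx) * (y - my)) / sqrt(sxx * syy)
  M2 <- (n - 1) * r^2
  list(r = r, M2 = M2, n = n,
       p = stats::pchisq(M2, df = 1L, lower.tail = FALSE),
       direction = if (r < 0) "shortened" else "lengthened",
       ok = TRUE, reason = NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery
#' rate, in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Test all tandem genes for 3'UTR length differences between two groups
#'
#' Runs [trend_table()] and [linear_trend_test()] on each profile for the
#' two sample groups, adjusts p-values by Benjamini-Hochberg over the
#' tested genes, and reports direction and mean standardized lengths.
#'
#' @param profiles A `tandem_profiles` list.
#' @param samples_a,samples_b Sample labels of the two groups (row scores 0
#'   and 1 respectively).
#' @param alpha FDR threshold used only for the `significant` flag.
#' @return data.frame per gene: `gene_id`, `n_sites`, `n`, `r`, `M2`, `p`,
#'   `q`, `direction`, `significant`, `mean_len_A`, `mean_len_B`,
#'   `skipped_reason` (`NA` for tested genes).
#' @export
apa_trend_test <- function(profiles, samples_a, samples_b, alpha = 0.05) {
  rows <- lapply(profiles, function(prof) {
    tt <- trend_table(prof, samples_a, samples_b)
    res <- if (tt$ok) linear_trend_test(tt$table, tt$col_scores)
           else list(r = NA_real_, M2 = NA_real_, n = sum(tt$table),
                     p = NA_real_, direction = NA_character_, ok = FALSE,
                     reason = tt$reason)
    wa <- rowSums(prof$counts[, samples_a, drop = FALSE])
    wb <- rowSums(prof$counts[, samples_b, drop = FALSE])
    data.frame(gene_id = prof$gene_id, n_sites = length(prof$std_len),
               n = res$n, r = res$r, M2 = res$M2, p = res$p,
               direction = res$direction,
               mean_len_A = if (sum(wa) > 0) sum(prof$std_len * wa) / sum(wa) else NA_real_,
               mean_len_B = if (sum(wb) > 0) sum(prof$std_len * wb) / sum(wb) else NA_real_,
               skipped_reason = if (res$ok) NA_character_ else res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      n = numeric(0), r = numeric(0), M2 = numeric(0),
                      p = numeric(0), q = numeric(0),
                      direction = character(0), significant = logical(0),
                      mean_len_A = numeric(0), mean_len_B = numeric(0),
                      skipped_reason = character(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$significant <- !is.na(out$q) & out$q < alpha
  out[, c("gene_id", "n_sites", "n", "r", "M2", "p", "q", "direction",
          "significant", "mean_len_A", "mean_len_B", "skipped_reason")]
}

#' Pairwise trend tests between two conditions
#'
#' Runs the trend test for every (replicate of A) x (replicate of B) pair,
#' as well as on the pooled counts, and summarizes how many pairs call each
#' gene in each direction.
#'
#' @inheritParams apa_trend_test
#' @return List with `pairs` (named list of per-pair result data.frames),
#'   `pooled` (result on pooled counts) and `overlap` (per-gene counts of
#'   significant shortened/lengthened calls across pairs).
#' @export
apa_trend_pairwise <- function(profiles, samples_a, samples_b, alpha = 0.05) {
  pairs <- list()
  for (sa in samples_a) for (sb in samples_b)
    pairs[[paste(sa, sb, sep = "_vs_")]] <-
      apa_trend_test(profiles, sa, sb, alpha)
  pooled <- apa_trend_test(profiles, samples_a, samples_b, alpha)
  genes <- pooled$gene_id
  sig_dir <- function(dir) {
    m <- vapply(pairs, function(d)
      d$significant & !is.na(d$direction) & d$direction == dir,
      logical(length(genes)))
    if (!is.matrix(m)) m <- matrix(m, nrow = length(genes))
    rowSums(m)
  }
  short_n <- sig_dir("shortened")
  long_n <- sig_dir("lengthened")
  list(pairs = pairs, pooled = pooled,
       overlap = data.frame(gene_id = genes, n_pairs = length(pairs),
                            shortened_in = short_n, lengthened_in = long_n,
                            stringsAsFactors = FALSE))
}
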