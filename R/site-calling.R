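# From per-sample mapped read 3'-ends to a filtered, thresholded,
# depth-normalized cross-sample poly(A)-site catalog.

#' Filter internal-priming artifact reads against the genome
#'
#' Oligo-d(T) priming on genomically encoded A-rich stretches produces read
#' 3'-ends that do not correspond to real cleavage sites. A read is removed
#' when the genomic window immediately downstream of its 3'-end (strand-aware,
#' starting at `pos + 1` in the direction of transcription) contains a run of
#' at least `a_run` consecutive A, or at least `a_window[1]` A in total within
#' the `a_window[2]`-nt window (default: 6 consecutive, or 7 of 10). Windows
#' truncated at a chromosome edge are evaluated on the available bases.
#'
#' @param reads data.frame with columns `chrom`, `pos` (1-based coordinate of
#'   the read's 3'-end base), `strand`, `sample` (extra columns pass through).
#' @param genome `DNAStringSet` covering every chromosome in `reads`.
#' @param a_run Minimum length of a consecutive-A run that triggers removal.
#' @param a_window Integer pair `(count, length)`: remove when at least
#'   `count` A occur in the downstream window of `length` nt.
#' @return List with elements `kept` and `removed`, both data.frames.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAAAAAAAAAACGT"))
#' rds <- data.frame(chrom = "chr1", pos = c(8L, 2L), strand = "+",
#'                   sample = "s1")
#' filter_internal_priming(rds, gen)$removed$pos  # read before the A-run
#' @export
filter_internal_priming <- function(reads, genome, a_run = 6L,
                                    a_window = c(7L, 10L)) {
  stopifnot(is.data.frame(reads), a_run >= 1L, length(a_window) == 2L,
            a_window[1] >= 1L, a_window[2] >= a_window[1])
  if (nrow(reads) == 0L)
    return(list(kept = reads, removed = reads))
  missing <- setdiff(unique(reads$chrom), names(genome))
  if (length(missing) > 0L)
    .stopf("genome lacks chromosome(s): %s", paste(missing, collapse = ", "))

  wlen <- as.integer(a_window[2])
  run_pat <- strrep("A", a_run)
  remove <- logical(nrow(reads))

  for (ch in unique(reads$chrom)) {
    idx <- which(reads$chrom == ch)
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    pos <- reads$pos[idx]
    bad <- pos < 1L | pos > len
    if (any(bad))
      .stopf("read beyond chromosome end: %s:%d (%s, sample %s)",
             ch, pos[which(bad)[1]], reads$strand[idx[which(bad)[1]]],
             reads$sample[idx[which(bad)[1]]])
    plus <- reads$strand[idx] == "+"
    win <- character(length(idx))
    if (any(plus))
      win[plus] <- .windows_from_seq(s, pos[plus] + 1L, pos[plus] + wlen)
    if (any(!plus))
      win[!plus] <- .revcomp(.windows_from_seq(s, pos[!plus] - wlen,
                                               pos[!plus] - 1L))
    remove[idx] <- grepl(run_pat, win, fixed = TRUE) |
      .base_count(win) >= a_window[1]
  }
  list(kept = reads[!remove, , drop = FALSE],
       removed = reads[remove, , drop = FALSE])
}

# Gap clustering of sorted unique positions with their read counts for one
# (chrom, strand); returns one row per cluster.
.cluster_positions <- function(pos, max_gap, chrom, strand) {
  tab <- table(pos)
  upos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  grp <- cumsum(c(1L, as.integer(diff(upos) > max_gap)))
  do.call(rbind, lapply(split(seq_along(upos), grp), function(i) {
    data.frame(chrom = chrom, strand = strand,
               rep_pos = .weighted_mode_pos(upos[i], cnt[i], strand),
               start = upos[i][1], end = upos[i][length(i)],
               count = sum(cnt[i]), stringsAsFactors = FALSE)
  }))
}

#' Cluster one sample's read 3'-ends into poly(A) sites
#'
#' Single-linkage gap clustering per chromosome and strand: positions are
#' sorted and a new cluster starts whenever the gap to the previous position
#' exceeds `max_gap`. The representative cleavage position is the position
#' with the most reads in the cluster, ties broken toward the 5' end of the
#' transcribed strand. Reads on different strands never co-cluster.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand` (one sample's
#'   reads; the `sample` column, if present, is ignored).
#' @param max_gap Maximum within-cluster gap between adjacent read
#'   positions, in nt.
#' @return data.frame with one row per site: `chrom`, `strand`, `rep_pos`,
#'   `start`, `end` (1-based inclusive span of member reads), `count`.
#' @examples
#' rds <- data.frame(chrom = "chr1", pos = c(100L, 101L, 103L, 200L),
#'                   strand = "+")
#' cluster_sample_sites(rds, max_gap = 24)
#' @export
cluster_sample_sites <- function(reads, max_gap = 24L) {
  stopifnot(is.data.frame(reads), max_gap >= 0L)
  empty <- data.frame(chrom = character(0), strand = character(0),
                      rep_pos = integer(0), start = integer(0),
                      end = integer(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  key <- paste(reads$chrom, reads$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(reads)), key), function(i)
    .cluster_positions(reads$pos[i], max_gap, reads$chrom[i[1]],
                       reads$strand[i[1]]))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$strand, res$rep_pos), , drop = FALSE]
}

#' Merge per-sample poly(A) sites into a cross-sample catalog
#'
#' Representative positions of per-sample sites are re-clustered with the
#' same gap rule; each merged site's representative position is the
#' read-count-weighted mode of its members' positions (ties toward the 5'
#' end of the transcribed strand) and per-sample raw counts are carried
#' into `reads.<sample>` columns. Summed counts are conserved exactly.
#'
#' @param site_lists Named list of per-sample site data.frames from
#'   [cluster_sample_sites()]; names are the sample labels.
#' @param max_gap Clustering gap in nt (use the same value as the
#'   per-sample clustering).
#' @return Site catalog data.frame: `site_id`, `chrom`, `strand`,
#'   `rep_pos`, `start`, `end`, and one `reads.<sample>` column per sample.
#' @export
merge_sites_across_samples <- function(site_lists, max_gap = 24L) {
  stopifnot(is.list(site_lists), !is.null(names(site_lists)))
  samples <- names(site_lists)
  comb <- do.call(rbind, lapply(samples, function(s) {
    d <- site_lists[[s]]
    if (nrow(d) == 0L) return(NULL)
    d$sample <- s
    d
  }))
  raw_names <- paste0("reads.", samples)
  if (is.null(comb) || nrow(comb) == 0L) {
    empty <- data.frame(site_id = character(0), chrom = character(0),
                        strand = character(0), rep_pos = integer(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
    for (cn in raw_names) empty[[cn]] <- numeric(0)
    return(empty)
  }

  key <- paste(comb$chrom, comb$strand, sep = "\r")
  merged <- lapply(split(seq_len(nrow(comb)), key), function(i) {
    d <- comb[i, , drop = FALSE]
    d <- d[order(d$rep_pos), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(d$rep_pos) > max_gap)))
    do.call(rbind, lapply(split(seq_len(nrow(d)), grp), function(j) {
      m <- d[j, , drop = FALSE]
      cnts <- vapply(samples, function(s)
        sum(m$count[m$sample == s]), numeric(1))
      row <- data.frame(chrom = m$chrom[1], strand = m$strand[1],
                        rep_pos = .weighted_mode_pos(m$rep_pos, m$count,
                                                     m$strand[1]),
                        start = min(m$start), end = max(m$end),
                        stringsAsFactors = FALSE)
      for (s in samples) row[[paste0("reads.", s)]] <- cnts[[s]]
      row
    }))
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$chrom, res$strand, res$rep_pos), , drop = FALSE]
  res <- cbind(site_id = sprintf("site%06d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Apply the minimum read-support threshold to a site catalog
#'
#' Retains sites whose raw read counts summed over all samples reach
#' `min_reads` (default 12, summed across samples).
#'
#' @param catalog Site catalog from [merge_sites_across_samples()].
#' @param min_reads Minimum cross-sample summed read count (inclusive).
#' @return Filtered catalog.
#' @export
apply_read_threshold <- function(catalog, min_reads = 12L) {
  stopifnot(min_reads >= 0L)
  if (nrow(catalog) == 0L) return(catalog)
  keep <- rowSums(raw_counts(catalog)) >= min_reads
  res <- catalog[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scale per-sample site counts to the shallowest sample
#'
#' Each sample's counts are multiplied by `min(totals) / total(sample)`, so
#' that after scaling every sample's total equals the smallest per-sample
#' total. Adds `norm.<sample>` columns.
#'
#' @param catalog Site catalog with `reads.<sample>` columns.
#' @param totals Optional named per-sample totals to scale by; defaults to
#'   the column sums of the catalog's raw counts.
#' @return Catalog with `norm.<sample>` columns appended.
#' @export
normalize_counts <- function(catalog, totals = NULL) {
  raw <- raw_counts(catalog)
  if (ncol(raw) == 0L) .stopf("catalog has no reads.<sample> columns")
  if (is.null(totals)) totals <- colSums(raw)
  totals <- totals[colnames(raw)]
  if (any(is.na(totals)))
    .stopf("totals missing for sample(s): %s",
           paste(colnames(raw)[is.na(totals)], collapse = ", "))
  if (any(totals == 0))
    .stopf("cannot scale: sample(s) with zero total reads: %s",
           paste(names(totals)[totals == 0], collapse = ", "))
  scale <- min(totals) / totals
  norm <- sweep(raw, 2L, scale, `*`)
  for (s in colnames(raw)) catalog[[paste0("norm.", s)]] <- norm[, s]
  catalog
}

#' Call poly(A) sites from multi-sample reads in one step
#'
#' Convenience wrapper: optionally filters internal-priming reads, clusters
#' each sample's 3'-ends, merges sites across samples, applies the read
#' threshold and normalizes counts.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand`, `sample`.
#' @param genome `DNAStringSet`; if `NULL`, the internal-priming filter is
#'   skipped.
#' @param max_gap Clustering gap (nt).
#' @param min_reads Cross-sample summed read threshold.
#' @param a_run,a_window Internal-priming filter parameters, see
#'   [filter_internal_priming()].
#' @param normalize Add depth-normalized counts.
#' @return List with `catalog` (the site catalog), `kept` and `removed`
#'   read data.frames.
#' @export
call_sites <- function(reads, genome = NULL, max_gap = 24L, min_reads = 12L,
                       a_run = 6L, a_window = c(7L, 10L), normalize = TRUE) {
  if (!is.null(genome)) {
    flt <- filter_internal_priming(reads, genome, a_run, a_window)
  } else {
    flt <- list(kept = reads, removed = reads[0, , drop = FALSE])
  }
  kept <- flt$kept
  samples <- sort(unique(reads$sample))
  per_sample <- lapply(samples, function(s)
    cluster_sample_sites(kept[kept$sample == s, , drop = FALSE], max_gap))
  names(per_sample) <- samples
  catalog <- merge_sites_across_samples(per_sample, max_gap)
  catalog <- apply_read_threshold(catalog, min_reads)
  if (normalize && nrow(catalog) > 0L &&
      all(colSums(raw_counts(catalog)) > 0))
    catalog <- normalize_counts(catalog)
  list(catalog = catalog, kept = kept, removed = flt$removed)
}
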