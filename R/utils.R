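# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

# Reverse-complement a character vector of DNA strings.
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Modal value of `pos` weighted by `w`, ties broken toward the 5' end of the
# transcribed strand ("+": smallest coordinate, "-": largest).
.weighted_mode_pos <- function(pos, w, strand) {
  agg <- rowsum(w, group = pos)
  cand <- as.numeric(rownames(agg))[agg[, 1L] == max(agg[, 1L])]
  if (strand == "+") min(cand) else max(cand)
}

# Extract windows [start, end] (1-based inclusive, plus-strand orientation)
# from one chromosome sequence given as a single character string; windows
# are clipped at the chromosome edges. Zero-width windows give "".
.windows_from_seq <- function(seq, start, end) {
  if (length(start) == 0L) return(character(0))
  len <- nchar(seq)
  s <- pmax(start, 1L)
  e <- pmin(end, len)
  out <- character(length(start))
  ok <- s <= e
  if (any(ok)) out[ok] <- substring(seq, s[ok], e[ok])
  out
}

# Count of a given base in each element of a character vector.
.base_count <- function(x, base = "A") {
  nchar(x) - nchar(gsub(base, "", x, fixed = TRUE))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Columns of a site catalog holding raw per-sample read counts.
.raw_cols <- function(catalog) grep("^reads\\.", names(catalog), value = TRUE)
.norm_cols <- function(catalog) grep("^norm\\.", names(catalog), value = TRUE)

#' Per-sample raw read counts of a site catalog
#'
#' @param catalog A site catalog as returned by
#'   [merge_sites_across_samples()] or [call_sites()].
#' @return Numeric matrix, sites x samples, column names are sample labels.
#' @export
raw_counts <- function(catalog) {
  cols <- .raw_cols(catalog)
  m <- as.matrix(catalog[, cols, drop = FALSE])
  colnames(m) <- sub("^reads\\.", "", cols)
  rownames(m) <- catalog$site_id
  m
}

#' Per-sample depth-normalized counts of a site catalog
#'
#' @inheritParams raw_counts
#' @return Numeric matrix, sites x samples (after [normalize_counts()]).
#' @export
norm_counts <- function(catalog) {
  cols <- .norm_cols(catalog)
  if (length(cols) == 0L)
    .stopf("catalog has no normalized counts; run normalize_counts() first")
  m <- as.matrix(catalog[, cols, drop = FALSE])
  colnames(m) <- sub("^norm\\.", "", cols)
  rownames(m) <- catalog$site_id
  m
}
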