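# On-disk interchange: FASTA genome, BED6 read 3'-ends, tab-separated gene
# models, known-site BED and catalog TSVs. All files use 0-based half-open
# coordinates; in memory the package works 1-based inclusive.

#' Write the genome as FASTA
#' @param genome `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return `DNAStringSet` named by the first token of each header.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write read 3'-ends as per-sample BED6 files
#'
#' Each read becomes one BED record: `chrom, pos-1, pos, sample, 1, strand`
#' (the interval covers the single 3'-end base, 0-based half-open).
#'
#' @param reads data.frame with `chrom`, `pos`, `strand`, `sample`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix>_<sample>.bed`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_reads_bed <- function(reads, dir, prefix = "reads") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- sort(unique(reads$sample))
  paths <- stats::setNames(file.path(dir, paste0(prefix, "_", samples, ".bed")),
                           samples)
  for (s in samples) {
    d <- reads[reads$sample == s, , drop = FALSE]
    bed <- data.frame(d$chrom, d$pos - 1L, d$pos, s, 1L, d$strand)
    utils::write.table(bed, paths[[s]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read read 3'-ends from BED6 files
#' @param paths One or more BED6 files written by [write_reads_bed()].
#' @return data.frame with `chrom`, `pos` (1-based 3'-end base), `strand`,
#'   `sample`.
#' @export
read_reads_bed <- function(paths) {
  out <- lapply(paths, function(p) {
    d <- utils::read.table(p, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "character"))
    data.frame(chrom = d$chrom, pos = d$end, strand = d$strand,
               sample = d$name, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write gene models as a tab-separated table
#'
#' Columns: `gene_id, cluster_id, chrom, strand, stop_codon_pos, utr_start,
#' utr_end` (plus CDS columns when present), 0-based half-open intervals and
#' 0-based positions on disk.
#'
#' @param genes Gene data.frame (1-based inclusive, as in the package).
#' @param path Output file.
#' @export
write_gene_models <- function(genes, path) {
  d <- genes
  d$stop_codon_pos <- d$stop_codon_pos - 1L
  d$utr_start <- d$utr_start - 1L           # half-open start
  if ("cds_start" %in% names(d)) d$cds_start <- d$cds_start - 1L
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models written by [write_gene_models()]
#' @param path Tab-separated gene-model file.
#' @return data.frame with 1-based inclusive coordinates.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$stop_codon_pos <- d$stop_codon_pos + 1L
  d$utr_start <- d$utr_start + 1L
  if ("cds_start" %in% names(d)) d$cds_start <- d$cds_start + 1L
  d
}

#' Write a known poly(A)-site catalog as BED6
#' @param sites data.frame with `chrom`, `pos` (1-based), `strand` and
#'   optionally `name`.
#' @param path Output file.
#' @export
write_known_sites_bed <- function(sites, path) {
  nm <- if ("name" %in% names(sites)) sites$name
        else sprintf("known%05d", seq_len(nrow(sites)))
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos, nm, 0L,
                    sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a known poly(A)-site BED6
#' @param path BED6 file.
#' @return data.frame with `chrom`, `pos` (1-based), `strand`, `name`.
#' @export
read_known_sites_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         stringsAsFactors = FALSE)
  data.frame(chrom = d$chrom, pos = d$end, strand = d$strand, name = d$name,
             stringsAsFactors = FALSE)
}

#' Write any result table as TSV
#' @param x data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
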