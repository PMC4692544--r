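# Gene-model construction keyed on stop codons, annotation of poly(A) sites
# by genomic category, poly(A)-signal hexamer detection and nucleotide
# composition profiles around cleavage sites.

#' @importFrom GenomicRanges GRanges findOverlaps distanceToNearest
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

.genes_gr <- function(genes, start_col, end_col) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes[[start_col]], genes[[end_col]]),
                         strand = genes$strand)
}

.sites_gr <- function(catalog) {
  GenomicRanges::GRanges(catalog$chrom,
                         IRanges::IRanges(catalog$rep_pos, width = 1L),
                         strand = catalog$strand)
}

#' Build the stop-codon-keyed gene dataset
#'
#' Genes can carry several transcript isoforms ending at the same stop
#' codon with 3'UTRs of different annotated lengths; for site-to-UTR
#' mapping only the largest 3'UTR per distinct stop codon is kept. Records
#' are grouped by `(chrom, strand, stop_codon_pos)` and the transcript with
#' the maximal 3'UTR length wins; equal lengths are broken toward the more
#' 3'-extending interval so the result is deterministic.
#'
#' @param transcripts data.frame with `gene_id`, `chrom`, `strand`,
#'   `stop_codon_pos`, `utr_start`, `utr_end` (1-based inclusive), and
#'   optionally `cluster_id`, `cds_start`, `cds_end`. Rows missing a stop
#'   codon or UTR are skipped with a warning.
#' @return data.frame with one record per distinct stop codon, with
#'   `utr_length` filled in; keys `(chrom, strand, stop_codon_pos)` unique.
#' @export
build_gene_dataset <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  need <- c("gene_id", "chrom", "strand", "stop_codon_pos",
            "utr_start", "utr_end")
  miss <- setdiff(need, names(transcripts))
  if (length(miss) > 0L)
    .stopf("transcripts lack column(s): %s", paste(miss, collapse = ", "))
  bad <- is.na(transcripts$stop_codon_pos) | is.na(transcripts$utr_start) |
    is.na(transcripts$utr_end)
  if (any(bad)) {
    .warnf("skipping %d transcript(s) without stop codon or 3'UTR", sum(bad))
    transcripts <- transcripts[!bad, , drop = FALSE]
  }
  if (nrow(transcripts) == 0L) return(transcripts)
  transcripts$utr_length <- transcripts$utr_end - transcripts$utr_start + 1L
  key <- paste(transcripts$chrom, transcripts$strand,
               transcripts$stop_codon_pos, sep = "\r")
  picked <- vapply(split(seq_len(nrow(transcripts)), key), function(i) {
    d <- transcripts[i, , drop = FALSE]
    best <- which(d$utr_length == max(d$utr_length))
    if (length(best) > 1L) {
      # tie: prefer the interval extending furthest 3' on the transcribed strand
      best <- if (d$strand[1] == "+") best[which.max(d$utr_end[best])]
              else best[which.min(d$utr_start[best])]
    }
    i[best[1]]
  }, integer(1))
  res <- transcripts[sort(unname(picked)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate poly(A) sites by genomic category
#'
#' Each site receives exactly one category by priority:
#' `known_polyA` (within `tolerance` nt of a site in the known catalog, same
#' strand) > `3'UTR` > `intron` > `CDS` > `1kb_downstream` > `noncoding` >
#' `intergenic`. Independently of the category, every site records which
#' genes' 3'UTRs contain it (`utr_hits`), the basis for selecting sites
#' usable in the tandem analysis.
#'
#' @param catalog Site catalog with `site_id`, `chrom`, `strand`, `rep_pos`.
#' @param genes Gene dataset from [build_gene_dataset()] (may carry
#'   `cds_start`/`cds_end` columns for the CDS category).
#' @param known_sites Optional data.frame of known poly(A) sites (`chrom`,
#'   `pos`, `strand`).
#' @param features Optional data.frame of extra features: `chrom`, `strand`,
#'   `start`, `end`, `type` with type in `intron`, `CDS`, `noncoding`.
#' @param tolerance Matching tolerance (nt) to known sites.
#' @param downstream_bp Extent of the downstream region beyond the 3'UTR
#'   end that is annotated `1kb_downstream`.
#' @return data.frame: `site_id`, `category`, `n_utr_hits`, `gene_id` (the
#'   single matched gene when `n_utr_hits == 1`, else `NA`), `utr_hit_ids`
#'   (comma-separated).
#' @export
assign_sites <- function(catalog, genes, known_sites = NULL, features = NULL,
                         tolerance = 24L, downstream_bp = 1000L) {
  n <- nrow(catalog)
  ann <- data.frame(site_id = catalog$site_id,
                    category = rep("intergenic", n),
                    n_utr_hits = integer(n),
                    gene_id = rep(NA_character_, n),
                    utr_hit_ids = rep("", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(ann)
  sgr <- .sites_gr(catalog)

  # 3'UTR hits (always computed; also feeds single-UTR selection)
  if (nrow(genes) > 0L) {
    ugr <- .genes_gr(genes, "utr_start", "utr_end")
    ov <- GenomicRanges::findOverlaps(sgr, ugr, ignore.strand = FALSE)
    hit_list <- split(genes$gene_id[S4Vectors::subjectHits(ov)],
                      factor(S4Vectors::queryHits(ov), levels = seq_len(n)))
    ann$n_utr_hits <- lengths(hit_list)
    ann$utr_hit_ids <- vapply(hit_list, paste, character(1), collapse = ",")
    ann$gene_id <- ifelse(ann$n_utr_hits == 1L, ann$utr_hit_ids, NA_character_)
  }

  in_feature <- function(feat_gr) {
    if (is.null(feat_gr) || length(feat_gr) == 0L) return(logical(n))
    GenomicRanges::countOverlaps(sgr, feat_gr, ignore.strand = FALSE) > 0L
  }
  feat_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand)
  }

  is_known <- logical(n)
  if (!is.null(known_sites) && nrow(known_sites) > 0L) {
    kgr <- GenomicRanges::GRanges(known_sites$chrom,
                                  IRanges::IRanges(known_sites$pos, width = 1L),
                                  strand = known_sites$strand)
    # width-1 ranges at distance d have gap d-1, so |pos - known| <= tolerance
    ov <- GenomicRanges::findOverlaps(sgr, kgr, maxgap = tolerance - 1L,
                                      ignore.strand = FALSE)
    is_known[unique(S4Vectors::queryHits(ov))] <- TRUE
  }

  is_utr <- ann$n_utr_hits > 0L

  ftab <- if (!is.null(features)) features else NULL
  is_intron <- in_feature(feat_gr(ftab[ftab$type == "intron", , drop = FALSE]))
  is_cds <- logical(n)
  if (all(c("cds_start", "cds_end") %in% names(genes)) && nrow(genes) > 0L)
    is_cds <- in_feature(.genes_gr(genes, "cds_start", "cds_end"))
  is_cds <- is_cds | in_feature(feat_gr(ftab[ftab$type == "CDS", , drop = FALSE]))

  is_down <- logical(n)
  if (nrow(genes) > 0L) {
    plus <- genes$strand == "+"
    dstart <- ifelse(plus, genes$utr_end + 1L, genes$utr_start - downstream_bp)
    dend <- ifelse(plus, genes$utr_end + downstream_bp, genes$utr_start - 1L)
    dgr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(pmax(dstart, 1L), dend),
                                  strand = genes$strand)
    is_down <- in_feature(dgr)
  }
  is_nc <- in_feature(feat_gr(ftab[ftab$type == "noncoding", , drop = FALSE]))

  # priority order, first match wins
  cat <- rep("intergenic", n)
  cat[is_nc] <- "noncoding"
  cat[is_down] <- "1kb_downstream"
  cat[is_cds] <- "CDS"
  cat[is_intron] <- "intron"
  cat[is_utr] <- "3'UTR"
  cat[is_known] <- "known_polyA"
  ann$category <- cat
  ann
}

#' Select sites mapped to exactly one 3'UTR
#'
#' Sites overlapping the 3'UTRs of two or more distinct stop-codon gene
#' records are ambiguous and excluded from the tandem analysis; sites with
#' exactly one 3'UTR hit are kept and labelled with that gene.
#'
#' @param catalog Site catalog.
#' @param annotations Output of [assign_sites()] for the same catalog.
#' @return Subset of `catalog` with a `gene_id` column appended.
#' @export
select_single_utr_sites <- function(catalog, annotations) {
  stopifnot(nrow(catalog) == nrow(annotations),
            all(catalog$site_id == annotations$site_id))
  keep <- annotations$n_utr_hits == 1L
  res <- catalog[keep, , drop = FALSE]
  res$gene_id <- annotations$gene_id[keep]
  rownames(res) <- NULL
  res
}

#' Canonical poly(A)-signal hexamer variants
#'
#' The twelve single-base variants of the AATAAA poly(A) signal, ordered by
#' strength: AATAAA and ATTAAA first, then the weaker variants.
#'
#' @return Character vector of 12 hexamers.
#' @export
apa_signal_hexamers <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATACA",
    "CATAAA", "AATATA", "GATAAA", "AATGAA", "ACTAAA", "AATAGA")
}

#' Detect the poly(A)-signal hexamer upstream of cleavage sites
#'
#' Scans the strand-aware upstream window (default -40..-1 relative to the
#' cleavage position, transcript orientation) for the hexamers in
#' `hexamers`, in priority order: the first hexamer in the list that occurs
#' anywhere in the window is reported, with the occurrence closest to the
#' cleavage site. The offset is the distance (nt) from the cleavage
#' position back to the hexamer start (e.g. a hexamer occupying -21..-16
#' has offset 21). Windows truncated at a contig edge are scanned over the
#' available bases.
#'
#' @param genome `DNAStringSet`.
#' @param sites data.frame with `chrom`, `rep_pos` (or `pos`), `strand`.
#' @param window Integer pair, upstream window relative to cleavage
#'   (negative offsets, default `c(-40, -1)`).
#' @param hexamers Hexamer list in priority order.
#' @return data.frame: `site_id` (if present), `hexamer` (`NA` if none
#'   found) and `offset` (nt upstream of cleavage to the hexamer start).
#' @export
detect_polya_signal <- function(genome, sites, window = c(-40L, -1L),
                                hexamers = apa_signal_hexamers()) {
  stopifnot(window[1] <= window[2], window[2] <= -1L)
  pos <- if ("rep_pos" %in% names(sites)) sites$rep_pos else sites$pos
  n <- length(pos)
  res <- data.frame(hexamer = rep(NA_character_, n),
                    offset = rep(NA_integer_, n), stringsAsFactors = FALSE)
  if ("site_id" %in% names(sites)) res <- cbind(site_id = sites$site_id, res,
                                                stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    s <- as.character(genome[[ch]])
    plus <- sites$strand[idx] == "+"
    win <- character(length(idx))
    # transcript-orientation window covering offsets window[1]..window[2]
    win[plus] <- .windows_from_seq(s, pos[idx][plus] + window[1],
                                   pos[idx][plus] + window[2])
    win[!plus] <- .revcomp(.windows_from_seq(s, pos[idx][!plus] - window[2],
                                             pos[idx][!plus] - window[1]))
    for (j in seq_along(idx)) {
      w <- win[j]
      wlen <- nchar(w)
      for (hx in hexamers) {
        occ <- gregexpr(hx, w, fixed = TRUE)[[1]]
        if (occ[1] > 0L) {
          at <- max(occ)  # occurrence closest to the cleavage site
          # last window base sits at offset window[2] from cleavage
          res$hexamer[idx[j]] <- hx
          res$offset[idx[j]] <- -(window[2]) + (wlen - at)
          break
        }
      }
    }
  }
  res
}

#' Nucleotide composition around cleavage sites
#'
#' Per-position base frequencies in the strand-aware flanking window
#' (reverse-complemented for minus-strand sites so that rows read in
#' transcript orientation). Row `0` is the cleavage position itself.
#'
#' @param genome `DNAStringSet`.
#' @param sites data.frame with `chrom`, `rep_pos` (or `pos`), `strand`.
#' @param flank Half-width of the window (nt).
#' @return Numeric matrix, rows named `-flank..flank`, columns `A,C,G,T`;
#'   each row sums to 1 over the sites with a defined base at that offset.
#' @export
nucleotide_profile <- function(genome, sites, flank = 50L) {
  stopifnot(flank >= 1L)
  pos <- if ("rep_pos" %in% names(sites)) sites$rep_pos else sites$pos
  width <- 2L * flank + 1L
  counts <- matrix(0, nrow = width, ncol = 4L,
                   dimnames = list(as.character(-flank:flank),
                                   c("A", "C", "G", "T")))
  if (length(pos) == 0L) return(counts)

  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    for (j in idx) {
      p <- pos[j]
      if (sites$strand[j] == "+") {
        lo <- p - flank; hi <- p + flank
        w <- .windows_from_seq(s, max(lo, 1L), min(hi, len))
        pad_l <- max(0L, 1L - lo); pad_r <- max(0L, hi - len)
      } else {
        lo <- p - flank; hi <- p + flank
        w <- .revcomp(.windows_from_seq(s, max(lo, 1L), min(hi, len)))
        pad_l <- max(0L, hi - len); pad_r <- max(0L, 1L - lo)
      }
      w <- paste0(strrep("N", pad_l), w, strrep("N", pad_r))
      bases <- strsplit(w, "")[[1]]
      for (b in c("A", "C", "G", "T")) {
        hitpos <- which(bases == b)
        if (length(hitpos) > 0L)
          counts[hitpos, b] <- counts[hitpos, b] + 1L
      }
    }
  }
  denom <- rowSums(counts)
  freq <- counts / ifelse(denom == 0, 1, denom)
  freq
}
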