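# Synthetic-data generator: a genome of single-gene chromosomes, a truth
# catalog of tandem poly(A) sites with condition-specific usage, and
# two-condition replicate read sets with cleavage jitter and internal-priming
# artifact reads. Everything downstream of read mapping is testable against
# the truth this module writes.

#' Generate a synthetic genome, gene models and poly(A)-site truth catalog
#'
#' Builds one chromosome per gene, each carrying a 5' pad, a CDS ending in a
#' stop codon, a 3'UTR with 1-4 tandem cleavage sites, and a 3' pad. Every
#' true site has the canonical AATAAA hexamer planted at -21..-16 relative
#' to the cleavage position and a T-rich element around +20 (transcript
#' orientation), matching the sequence context of genuine poly(A) sites.
#' Background sequence is i.i.d. uniform over A/C/G/T, rejection-resampled
#' so that no accidental AATAAA occurs within -40..-1 of a true site. One
#' 10-nt poly(A) run (an internal-priming trap) is placed inside each 3'UTR,
#' at least 80 nt from any true site.
#'
#' Per-gene site-usage proportions are drawn from a symmetric Dirichlet(3)
#' with a 0.05 floor per site; in condition B a configured fraction of
#' multi-site genes has `effect_size` usage probability shifted onto the
#' most proximal site (3'UTR shortening), the remaining sites rescaled.
#'
#' @param config A [sim_config()].
#' @return A list of class `apa_sim` with elements:
#'   \describe{
#'     \item{genome}{`DNAStringSet`, one entry per chromosome.}
#'     \item{genes}{data.frame of gene models (1-based inclusive
#'       coordinates): `gene_id`, `cluster_id`, `chrom`, `strand`,
#'       `stop_codon_pos` (last base of the stop codon), `utr_start`,
#'       `utr_end`, `cds_start`, `cds_end`, `utr_length`.}
#'     \item{truth}{list with `sites` (per-site cleavage position,
#'       3'UTR offset, rank, per-condition usage), `traps` (A-run loci and
#'       the 3'-end position internal priming produces there) and `genes`
#'       (number of sites, shifted flag).}
#'   }
#' @examples
#' sim <- simulate_apa_genome(sim_config(n_genes = 5, seed = 2))
#' names(sim)
#' @export
simulate_apa_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes

  empty_genes <- data.frame(gene_id = character(0), cluster_id = character(0),
                            chrom = character(0), strand = character(0),
                            stop_codon_pos = integer(0), utr_start = integer(0),
                            utr_end = integer(0), cds_start = integer(0),
                            cds_end = integer(0), utr_length = integer(0),
                            stringsAsFactors = FALSE)
  empty_sites <- data.frame(gene_id = character(0), chrom = character(0),
                            strand = character(0), pos = integer(0),
                            utr_offset = integer(0), site_rank = integer(0),
                            prop_A = numeric(0), prop_B = numeric(0),
                            stringsAsFactors = FALSE)
  empty_traps <- data.frame(gene_id = character(0), chrom = character(0),
                            strand = character(0), read_pos = integer(0),
                            run_start = integer(0), run_end = integer(0),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(genome = Biostrings::DNAStringSet(),
                          genes = empty_genes,
                          truth = list(sites = empty_sites, traps = empty_traps,
                                       genes = data.frame(gene_id = character(0),
                                                          n_sites = integer(0),
                                                          shifted = logical(0))),
                          config = config),
                     class = "apa_sim"))
  }

  gene_id <- sprintf("gene%04d", seq_len(n))
  chrom <- sprintf("chr%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  k_opts <- as.integer(names(config$sites_per_gene))
  k <- k_opts[sample.int(length(k_opts), n, replace = TRUE,
                         prob = config$sites_per_gene)]

  # Which multi-site genes carry the condition-B proximal shift.
  multi <- which(k >= 2L)
  n_shift <- round(config$shortening_fraction * length(multi))
  shifted <- rep(FALSE, n)
  if (n_shift > 0L)
    shifted[sample(multi, n_shift)] <- TRUE

  pad5 <- 200L; cds_len <- 300L; pad3 <- 1100L
  seqs <- character(n)
  genes <- vector("list", n)
  sites <- vector("list", n)
  traps <- vector("list", n)

  rdirich_floor <- function(kk, alpha = 3, floor = 0.05) {
    if (kk == 1L) return(1)
    repeat {
      g <- stats::rgamma(kk, alpha)
      p <- g / sum(g)
      if (min(p) >= floor) return(p)
    }
  }

  for (g in seq_len(n)) {
    kk <- k[g]
    need <- config$min_utr_offset + (kk - 1L) * config$min_site_spacing + 40L
    utr_len <- max(need, sample(config$utr_length_range[1]:config$utr_length_range[2], 1L))
    # Spaced uniform offsets: guaranteed pairwise separation ~min_site_spacing.
    slack <- utr_len - config$min_utr_offset - (kk - 1L) * config$min_site_spacing
    u <- sort(stats::runif(kk, 0, slack))
    off <- pmin(utr_len,
                as.integer(round(config$min_utr_offset +
                                   (seq_len(kk) - 1L) * config$min_site_spacing + u)))

    cds_start <- pad5 + 1L; cds_end <- pad5 + cds_len
    stop_pos <- cds_end
    utr_start <- cds_end + 1L; utr_end <- cds_end + utr_len
    L <- utr_end + pad3
    site_pos <- stop_pos + off

    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (sp in site_pos) {
      seqv[(sp - 21L):(sp - 16L)] <- c("A", "A", "T", "A", "A", "A")
      seqv[(sp + 17L):(sp + 24L)] <- "T"
    }

    # Internal-priming trap: a 10-A run in the 3'UTR, >= 80 nt from any site.
    cand <- (utr_start + 20L):(utr_end - 30L)
    for (sp in site_pos)
      cand <- cand[abs(cand - sp) >= 80L & abs(cand + 9L - sp) >= 80L]
    trap_start <- if (length(cand) > 0L) cand[sample.int(length(cand), 1L)] else NA_integer_
    if (!is.na(trap_start)) seqv[trap_start:(trap_start + 9L)] <- "A"

    # Reject accidental AATAAA within -40..-1 of each site (keep the planted one).
    for (sp in site_pos) {
      ws <- sp - 40L; we <- sp - 1L
      planted <- (sp - 21L):(sp - 16L)
      for (iter in 1:50) {
        w <- paste(seqv[ws:we], collapse = "")
        hits <- gregexpr("AATAAA", w, fixed = TRUE)[[1]]
        hits <- hits[hits > 0L]
        bad <- hits[ws + hits - 1L != sp - 21L]
        if (length(bad) == 0L) break
        for (b in bad) {
          idx <- setdiff((ws + b - 1L):(ws + b + 4L), planted)
          seqv[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
        }
      }
    }

    trap_read <- if (!is.na(trap_start)) trap_start - 1L else NA_integer_
    run_lo <- trap_start; run_hi <- if (!is.na(trap_start)) trap_start + 9L else NA_integer_

    if (strand[g] == "-") {
      # Build happened in transcript space; flip to the genome's plus strand.
      seqv <- rev(chartr("ACGT", "TGCA", seqv))
      flip <- function(p) L - p + 1L
      site_pos <- flip(site_pos)
      stop_pos <- flip(stop_pos)
      tmp <- c(flip(utr_end), flip(utr_start)); utr_start <- tmp[1]; utr_end <- tmp[2]
      tmp <- c(flip(cds_end), flip(cds_start)); cds_start <- tmp[1]; cds_end <- tmp[2]
      if (!is.na(trap_read)) {
        trap_read <- flip(trap_read)
        tmp <- c(flip(run_hi), flip(run_lo)); run_lo <- tmp[1]; run_hi <- tmp[2]
      }
    }
    seqs[g] <- paste(seqv, collapse = "")

    genes[[g]] <- data.frame(gene_id = gene_id[g], cluster_id = gene_id[g],
                             chrom = chrom[g], strand = strand[g],
                             stop_codon_pos = stop_pos,
                             utr_start = utr_start, utr_end = utr_end,
                             cds_start = cds_start, cds_end = cds_end,
                             utr_length = utr_len, stringsAsFactors = FALSE)

    pA <- rdirich_floor(kk)
    pB <- pA
    if (shifted[g]) {
      pB1 <- min(pA[1] + config$effect_size, 0.95)
      pB <- c(pB1, pA[-1] * (1 - pB1) / (1 - pA[1]))
    }
    sites[[g]] <- data.frame(gene_id = gene_id[g], chrom = chrom[g],
                             strand = strand[g], pos = site_pos,
                             utr_offset = off, site_rank = seq_len(kk),
                             prop_A = pA, prop_B = pB,
                             stringsAsFactors = FALSE)
    if (!is.na(trap_read))
      traps[[g]] <- data.frame(gene_id = gene_id[g], chrom = chrom[g],
                               strand = strand[g], read_pos = trap_read,
                               run_start = run_lo, run_end = run_hi,
                               stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom
  trap_df <- if (length(traps) > 0 && any(!vapply(traps, is.null, TRUE)))
    do.call(rbind, traps[!vapply(traps, is.null, TRUE)]) else empty_traps

  structure(list(genome = genome,
                 genes = do.call(rbind, genes),
                 truth = list(sites = do.call(rbind, sites),
                              traps = trap_df,
                              genes = data.frame(gene_id = gene_id, n_sites = k,
                                                 shifted = shifted,
                                                 stringsAsFactors = FALSE)),
                 config = config),
            class = "apa_sim")
}

#' @export
print.apa_sim <- function(x, ...) {
  cat("apa_sim:", length(x$genome), "chromosomes,",
      nrow(x$truth$sites), "true poly(A) sites,",
      sum(x$truth$genes$shifted), "genes with a condition effect\n")
  invisible(x)
}

#' Simulate per-sample read 3'-ends from a synthetic truth catalog
#'
#' For each sample (two conditions x `n_replicates`), draws a Poisson read
#' depth, allocates an `internal_priming_rate` fraction of reads to A-run
#' trap loci (3'-end lands immediately 5' of the run), distributes the rest
#' evenly across genes and multinomially across each gene's sites with the
#' condition's usage proportions, and jitters true-read positions by a
#' discretized Gaussian truncated at +/- 3 sd.
#'
#' @param sim An `apa_sim` from [simulate_apa_genome()].
#' @param config The same [sim_config()] used to build `sim` (defaults to
#'   the one stored in `sim`).
#' @return data.frame of read 3'-ends: `chrom`, `pos` (1-based coordinate of
#'   the last transcribed base), `strand`, `sample`, plus truth columns
#'   `artifact` (internal-priming flag), `gene_id` and `site_rank`.
#' @examples
#' sim <- simulate_apa_genome(sim_config(n_genes = 5, depth_per_sample = 200, seed = 2))
#' reads <- simulate_reads(sim)
#' table(reads$sample)
#' @export
simulate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "apa_sim"))
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), sample = character(0),
                      artifact = logical(0), gene_id = character(0),
                      site_rank = integer(0), stringsAsFactors = FALSE)
  if (config$n_genes == 0L || nrow(sim$truth$sites) == 0L) return(empty)

  sites <- sim$truth$sites
  traps <- sim$truth$traps
  n_genes <- config$n_genes
  sd <- config$cleavage_jitter_sd
  site_by_gene <- split(sites, sites$gene_id)

  jitter <- function(m) {
    if (m == 0L || sd == 0) return(integer(m))
    j <- as.integer(round(stats::rnorm(m, 0, sd)))
    bound <- 3 * sd
    while (any(abs(j) > bound))
      j[abs(j) > bound] <- as.integer(round(stats::rnorm(sum(abs(j) > bound), 0, sd)))
    j
  }

  out <- vector("list", 2L * config$n_replicates)
  si <- 0L
  for (cond in c("A", "B")) {
    pcol <- if (cond == "A") "prop_A" else "prop_B"
    for (rep_i in seq_len(config$n_replicates)) {
      si <- si + 1L
      smp <- paste0(cond, "_", rep_i)
      depth <- stats::rpois(1L, config$depth_per_sample)
      if (depth == 0L) {
        .warnf("sample %s drew zero reads", smp)
        next
      }
      n_art <- stats::rbinom(1L, depth, config$internal_priming_rate)
      if (n_art > 0L && nrow(traps) == 0L) n_art <- 0L
      n_true <- depth - n_art

      per_gene <- as.vector(stats::rmultinom(1L, n_true, rep(1, n_genes)))
      chunks <- vector("list", n_genes + 1L)
      for (g in seq_len(n_genes)) {
        m <- per_gene[g]
        if (m == 0L) next
        gs <- site_by_gene[[sim$truth$genes$gene_id[g]]]
        cnt <- as.vector(stats::rmultinom(1L, m, gs[[pcol]]))
        pos <- rep(gs$pos, cnt) + jitter(m)
        chunks[[g]] <- data.frame(chrom = gs$chrom[1], pos = pos,
                                  strand = gs$strand[1], sample = smp,
                                  artifact = FALSE, gene_id = gs$gene_id[1],
                                  site_rank = rep(gs$site_rank, cnt),
                                  stringsAsFactors = FALSE)
      }
      if (n_art > 0L) {
        ti <- sample.int(nrow(traps), n_art, replace = TRUE)
        chunks[[n_genes + 1L]] <- data.frame(chrom = traps$chrom[ti],
                                             pos = traps$read_pos[ti],
                                             strand = traps$strand[ti],
                                             sample = smp, artifact = TRUE,
                                             gene_id = traps$gene_id[ti],
                                             site_rank = NA_integer_,
                                             stringsAsFactors = FALSE)
      }
      out[[si]] <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate tandem-site count profiles directly (no genome)
#'
#' Generates per-gene multinomial read counts over 2-4 tandem sites with
#' standardized 3'UTR lengths, for two conditions with replicates — the
#' count layer of the full simulator, used for statistical calibration of
#' the trend test at scale.
#'
#' @param n_genes Number of tandem (multi-site) genes.
#' @param sites_prob Probabilities over 2, 3, 4 sites per gene.
#' @param reads_per_sample Expected reads per gene per sample (Poisson).
#' @param n_replicates Replicates per condition.
#' @param shortening_fraction Fraction of genes with a proximal usage shift
#'   in condition B.
#' @param effect_size Usage-probability shift onto the proximal site.
#' @param seed Integer seed.
#' @return List with `profiles` (a `tandem_profiles` list usable by
#'   [apa_trend_test()]), `truth` (per-gene shifted flag) and `samples`.
#' @export
simulate_tandem_counts <- function(n_genes = 1000L,
                                   sites_prob = c("2" = 0.5, "3" = 0.3, "4" = 0.2),
                                   reads_per_sample = 100L,
                                   n_replicates = 3L,
                                   shortening_fraction = 0.1,
                                   effect_size = 0.3,
                                   seed = 1L) {
  stopifnot(n_genes >= 0, reads_per_sample >= 1, n_replicates >= 1,
            shortening_fraction >= 0, shortening_fraction <= 1,
            effect_size >= 0, effect_size <= 1)
  set.seed(seed)
  samples <- as.vector(vapply(c("A", "B"), function(cond)
    paste0(cond, "_", seq_len(n_replicates)), character(n_replicates)))
  k_opts <- as.integer(names(sites_prob))
  k <- k_opts[sample.int(length(k_opts), n_genes, replace = TRUE,
                         prob = sites_prob)]
  shifted <- rep(FALSE, n_genes)
  n_shift <- round(shortening_fraction * n_genes)
  if (n_shift > 0L) shifted[sample.int(n_genes, n_shift)] <- TRUE

  profiles <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    kk <- k[g]
    std <- c(sort(stats::runif(kk - 1L, 0.15, 0.9)), 1)
    repeat {
      gam <- stats::rgamma(kk, 3)
      pA <- gam / sum(gam)
      if (min(pA) >= 0.05) break
    }
    pB <- pA
    if (shifted[g]) {
      pB1 <- min(pA[1] + effect_size, 0.95)
      pB <- c(pB1, pA[-1] * (1 - pB1) / (1 - pA[1]))
    }
    cnt <- matrix(0L, nrow = kk, ncol = length(samples),
                  dimnames = list(NULL, samples))
    for (s in samples) {
      p <- if (startsWith(s, "A")) pA else pB
      cnt[, s] <- as.vector(stats::rmultinom(1L, stats::rpois(1L, reads_per_sample), p))
    }
    gid <- sprintf("gene%05d", g)
    profiles[[g]] <- structure(list(gene_id = gid, chrom = NA_character_,
                                    strand = NA_character_,
                                    site_id = paste0(gid, ".s", seq_len(kk)),
                                    rep_pos = rep(NA_integer_, kk),
                                    utr_len = round(std * 1000),
                                    std_len = std, counts = cnt),
                               class = "tandem_profile")
    names(profiles)[g] <- gid
  }
  list(profiles = structure(profiles, class = "tandem_profiles"),
       truth = data.frame(gene_id = names(profiles), n_sites = k,
                          shifted = shifted, stringsAsFactors = FALSE),
       samples = samples)
}

#' Simulate stop-codon isoform clusters (count level)
#'
#' Generates per-cluster proximal/distal isoform read counts for two
#' conditions with replicates; a fraction of clusters has the proximal-share
#' shifted in condition B, in a randomly chosen direction. Used to check
#' that the isoform-switch test recovers planted switches with the right
#' direction.
#'
#' @param n_clusters Number of gene clusters (each with two stop-codon
#'   isoforms).
#' @param n_replicates Replicates per condition.
#' @param reads_per_cluster Expected reads per cluster per sample (Poisson).
#' @param switch_fraction Fraction of clusters with a planted switch.
#' @param effect_size Shift of the proximal-isoform share in condition B.
#' @param seed Integer seed.
#' @return List with `counts` (cluster x sample proximal/distal counts, long
#'   format) and `truth` (shifted flag and planted direction).
#' @export
simulate_switch_clusters <- function(n_clusters = 200L, n_replicates = 3L,
                                     reads_per_cluster = 200L,
                                     switch_fraction = 0.2,
                                     effect_size = 0.3, seed = 1L) {
  set.seed(seed)
  samples <- as.vector(vapply(c("A", "B"), function(cond)
    paste0(cond, "_", seq_len(n_replicates)), character(n_replicates)))
  cluster_id <- sprintf("cluster%04d", seq_len(n_clusters))
  shifted <- rep(FALSE, n_clusters)
  n_shift <- round(switch_fraction * n_clusters)
  if (n_shift > 0L) shifted[sample.int(n_clusters, n_shift)] <- TRUE
  direction <- ifelse(shifted,
                      sample(c("proximal", "distal"), n_clusters, replace = TRUE),
                      NA_character_)
  pA <- stats::runif(n_clusters, 0.2, 0.8)
  pB <- pA
  pB[shifted & direction == "proximal"] <-
    pmin(pA[shifted & direction == "proximal"] + effect_size, 0.95)
  pB[shifted & direction == "distal"] <-
    pmax(pA[shifted & direction == "distal"] - effect_size, 0.05)

  rows <- vector("list", n_clusters * length(samples))
  i <- 0L
  for (g in seq_len(n_clusters)) {
    for (s in samples) {
      i <- i + 1L
      p <- if (startsWith(s, "A")) pA[g] else pB[g]
      tot <- stats::rpois(1L, reads_per_cluster)
      prox <- stats::rbinom(1L, tot, p)
      rows[[i]] <- data.frame(cluster_id = cluster_id[g], sample = s,
                              proximal = prox, distal = tot - prox,
                              stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, rows),
       truth = data.frame(cluster_id = cluster_id, shifted = shifted,
                          direction = direction, stringsAsFactors = FALSE))
}
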