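# Stop-codon-keyed gene dataset, category assignment, single-UTR selection,
# poly(A)-signal detection and nucleotide composition.

tx_row <- function(gene_id, stop, us, ue, strand = "+", chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             stop_codon_pos = stop, utr_start = us, utr_end = ue,
             stringsAsFactors = FALSE)
}

test_that("largest 3'UTR per stop codon wins; distinct stop codons stay separate", {
  tx <- rbind(tx_row("t1", 500, 501, 1000),   # length 500
              tx_row("t2", 500, 501, 1300),   # length 800, same stop codon
              tx_row("t3", 2000, 2001, 2400)) # different stop codon
  gs <- build_gene_dataset(tx)
  expect_equal(nrow(gs), 2)
  expect_equal(gs$gene_id[gs$stop_codon_pos == 500], "t2")
  expect_equal(gs$utr_length[gs$stop_codon_pos == 500], 800)
})

test_that("equal-length ties keep the more 3'-extending interval, deterministically", {
  tx_plus <- rbind(tx_row("p1", 500, 501, 1000),
                   tx_row("p2", 500, 601, 1100))   # same length, extends further 3'
  expect_equal(build_gene_dataset(tx_plus)$gene_id, "p2")
  tx_minus <- rbind(tx_row("m1", 1000, 500, 999, strand = "-"),
                    tx_row("m2", 1000, 400, 899, strand = "-"))
  expect_equal(build_gene_dataset(tx_minus)$gene_id, "m2")
  # deterministic across repeated calls
  expect_identical(build_gene_dataset(tx_plus), build_gene_dataset(tx_plus))
})

test_that("transcripts without stop codon or UTR are skipped with a warning", {
  tx <- rbind(tx_row("ok", 500, 501, 1000),
              tx_row("bad", NA, 501, 1000))
  expect_warning(gs <- build_gene_dataset(tx), "skipping")
  expect_equal(gs$gene_id, "ok")
})

test_that("unique (chrom, strand, stop codon) keys in the gene dataset", {
  sim <- simulate_apa_genome(sim_config(n_genes = 30, seed = 41))
  gs <- build_gene_dataset(sim$genes)
  key <- paste(gs$chrom, gs$strand, gs$stop_codon_pos)
  expect_equal(anyDuplicated(key), 0)
})

make_catalog <- function(chrom, pos, strand) {
  data.frame(site_id = sprintf("s%02d", seq_along(pos)), chrom = chrom,
             strand = strand, rep_pos = pos, start = pos, end = pos,
             reads.x = 10, stringsAsFactors = FALSE)
}

test_that("category priority: known > 3'UTR > CDS > downstream > intergenic", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      stop_codon_pos = 500, utr_start = 501, utr_end = 1000,
                      cds_start = 201, cds_end = 500, stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", pos = 600, strand = "+")
  cat1 <- make_catalog("chr1", c(610L, 800L, 300L, 1500L, 5000L), "+")
  ann <- assign_sites(cat1, genes, known_sites = known)
  expect_equal(ann$category,
               c("known_polyA", "3'UTR", "CDS", "1kb_downstream", "intergenic"))
  # known match is strand-specific and tolerance-bounded (24 nt, symmetric)
  cat2 <- make_catalog("chr1", c(624L, 625L), "+")
  ann2 <- assign_sites(cat2, genes, known_sites = known)
  expect_equal(ann2$category, c("known_polyA", "3'UTR"))
  # opposite strand: no known match, no UTR hit
  cat3 <- make_catalog("chr1", 610L, "-")
  expect_equal(assign_sites(cat3, genes, known_sites = known)$category,
               "intergenic")
})

test_that("intron and noncoding features are honored in priority order", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      stop_codon_pos = 500, utr_start = 501, utr_end = 1000,
                      stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "chr1", strand = "+",
                      start = c(3000, 6000), end = c(3500, 6500),
                      type = c("intron", "noncoding"), stringsAsFactors = FALSE)
  cat1 <- make_catalog("chr1", c(3100L, 6100L), "+")
  ann <- assign_sites(cat1, genes, features = feats)
  expect_equal(ann$category, c("intron", "noncoding"))
})

test_that("every site gets exactly one category; counts sum to catalog size", {
  sim <- simulate_apa_genome(sim_config(n_genes = 30, seed = 42))
  reads <- simulate_reads(sim)
  cs <- call_sites(reads[, c("chrom", "pos", "strand", "sample")], sim$genome)
  ann <- assign_sites(cs$catalog, build_gene_dataset(sim$genes))
  expect_equal(nrow(ann), nrow(cs$catalog))
  expect_equal(sum(table(ann$category)), nrow(cs$catalog))
  expect_false(any(is.na(ann$category)))
})

test_that("single-UTR selection keeps exactly the unambiguous sites", {
  # two genes with overlapping UTRs on the same strand
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      stop_codon_pos = c(500, 700),
                      utr_start = c(501, 701), utr_end = c(1000, 1600),
                      stringsAsFactors = FALSE)
  cat1 <- make_catalog("chr1", c(800L, 1500L), "+")
  ann <- assign_sites(cat1, genes)
  expect_equal(ann$n_utr_hits, c(2L, 1L))
  sel <- select_single_utr_sites(cat1, ann)
  expect_equal(sel$site_id, "s02")
  expect_equal(sel$gene_id, "g2")
})

test_that("simulated layout has non-overlapping genes: selection is the identity on 3'UTR sites", {
  sim <- simulate_apa_genome(sim_config(n_genes = 20, seed = 43))
  reads <- simulate_reads(sim)
  cs <- call_sites(reads[, c("chrom", "pos", "strand", "sample")], sim$genome)
  ann <- assign_sites(cs$catalog, build_gene_dataset(sim$genes))
  in_utr <- ann$category == "3'UTR"
  sel <- select_single_utr_sites(cs$catalog, ann)
  expect_equal(sort(sel$site_id), sort(ann$site_id[in_utr]))
})

test_that("signal detection finds hexamers at the right offset with priority order", {
  # AATAAA planted at -21..-16 of a site at position 100
  up <- paste0(strrep("C", 59), "G", strrep("C", 18), "AATAAA",
               strrep("C", 16))  # hexamer at 79..84; site at 100
  gen <- Biostrings::DNAStringSet(c(chr1 = paste0(up, strrep("C", 20))))
  st <- data.frame(chrom = "chr1", pos = 100L, strand = "+")
  sig <- detect_polya_signal(gen, st)
  expect_equal(sig$hexamer, "AATAAA")
  expect_equal(sig$offset, 21L)

  # both ATTAAA (offset 30) and AATAAA (offset 18): AATAAA wins by priority
  up2 <- paste0(strrep("C", 69), "ATTAAA", strrep("C", 6), "AATAAA",
                strrep("C", 13))
  gen2 <- Biostrings::DNAStringSet(c(chr1 = up2))
  st2 <- data.frame(chrom = "chr1", pos = 100L, strand = "+")
  sig2 <- detect_polya_signal(gen2, st2)
  expect_equal(sig2$hexamer, "AATAAA")
  expect_equal(sig2$offset, 18L)

  # window of non-signal sequence: none
  gen3 <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 200)))
  sig3 <- detect_polya_signal(gen3, st2)
  expect_true(is.na(sig3$hexamer))
})

test_that("signal detection is strand-aware", {
  # minus-strand site at 50: upstream window is genomic 51..90 revcomp'd;
  # plant TTTATT at genomic 66..71 -> transcript AATAAA at offset -21..-16
  s <- paste0(strrep("C", 65), "TTTATT", strrep("C", 40))
  gen <- Biostrings::DNAStringSet(c(chr1 = s))
  st <- data.frame(chrom = "chr1", pos = 50L, strand = "-")
  sig <- detect_polya_signal(gen, st)
  expect_equal(sig$hexamer, "AATAAA")
  expect_equal(sig$offset, 21L)
})

test_that("nucleotide profile rows sum to one and read in transcript orientation", {
  gen <- Biostrings::DNAStringSet(c(chr1 = "AACGTTTTTT"))
  st <- data.frame(chrom = "chr1", pos = 4L, strand = "+")
  prof <- nucleotide_profile(gen, st, flank = 1)
  expect_equal(dim(prof), c(3L, 4L))
  expect_equal(unname(rowSums(prof)), rep(1, 3))
  expect_equal(unname(prof["-1", "C"]), 1)
  expect_equal(unname(prof["0", "G"]), 1)
  expect_equal(unname(prof["1", "T"]), 1)
  # minus strand on the same spot: complemented and reversed
  stm <- data.frame(chrom = "chr1", pos = 4L, strand = "-")
  pm <- nucleotide_profile(gen, stm, flank = 1)
  expect_equal(unname(pm["-1", "A"]), 1)  # genomic T downstream -> transcript A upstream
  expect_equal(unname(pm["0", "C"]), 1)
  expect_equal(unname(pm["1", "G"]), 1)
})

test_that("synthetic sites show the A-rich region upstream of cleavage", {
  sim <- simulate_apa_genome(sim_config(n_genes = 30, seed = 44))
  prof <- nucleotide_profile(sim$genome, sim$truth$sites, flank = 50)
  a_rich <- mean(prof[as.character(-25:-10), "A"])
  background <- mean(prof[as.character(-50:-41), "A"])
  expect_gt(a_rich, background)
})
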