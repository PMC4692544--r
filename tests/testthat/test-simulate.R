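# Synthetic-data generator: determinism, construction invariants, and the
# statistical structure of emitted reads.

test_that("config validation rejects invalid parameter values", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(internal_priming_rate = 1.2), "internal_priming_rate")
  expect_error(sim_config(shortening_fraction = -0.1), "shortening_fraction")
  expect_error(sim_config(utr_length_range = c(500, 300)), "utr_length_range")
  expect_error(sim_config(sites_per_gene = c("1" = -0.5, "2" = 1.5)),
               "sites_per_gene")
})

test_that("degenerate input: zero genes give an empty genome and catalog", {
  sim <- simulate_apa_genome(sim_config(n_genes = 0))
  expect_length(sim$genome, 0)
  expect_equal(nrow(sim$genes), 0)
  expect_equal(nrow(sim$truth$sites), 0)
  expect_equal(nrow(simulate_reads(sim)), 0)
})

test_that("fixed seed gives byte-identical genome, truth and reads", {
  cfg <- sim_config(n_genes = 20, depth_per_sample = 500, seed = 11)
  s1 <- simulate_apa_genome(cfg)
  s2 <- simulate_apa_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_reads(s1), simulate_reads(s2))
})

test_that("distinct seeds give distinct read sets", {
  s1 <- simulate_apa_genome(sim_config(n_genes = 10, depth_per_sample = 500,
                                       seed = 1))
  s2 <- simulate_apa_genome(sim_config(n_genes = 10, depth_per_sample = 500,
                                       seed = 2))
  expect_false(identical(as.character(s1$genome), as.character(s2$genome)))
  expect_false(identical(simulate_reads(s1), simulate_reads(s2)))
})

test_that("site count, hexamer placement and trap structure follow construction", {
  cfg <- sim_config(n_genes = 100, sites_per_gene = c("2" = 1), seed = 3)
  sim <- simulate_apa_genome(cfg)
  expect_equal(nrow(sim$truth$sites), 200)  # 100 genes x exactly 2 sites

  # every true site has AATAAA at -21..-16 (transcript orientation)
  sites <- sim$truth$sites
  hex <- vapply(seq_len(nrow(sites)), function(i) {
    s <- as.character(sim$genome[[sites$chrom[i]]])
    p <- sites$pos[i]
    if (sites$strand[i] == "+") substring(s, p - 21, p - 16)
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(s, p + 16, p + 21))))
  }, character(1))
  expect_true(all(hex == "AATAAA"))

  # proportions sum to 1 in both conditions; sites inside their 3'UTR
  pa <- tapply(sites$prop_A, sites$gene_id, sum)
  pb <- tapply(sites$prop_B, sites$gene_id, sum)
  expect_true(all(abs(pa - 1) < 1e-12) && all(abs(pb - 1) < 1e-12))
  gm <- sim$genes[match(sites$gene_id, sim$genes$gene_id), ]
  expect_true(all(sites$pos >= gm$utr_start & sites$pos <= gm$utr_end))

  # traps are 10-A runs (transcript orientation) not coinciding with sites
  traps <- sim$truth$traps
  runbase <- vapply(seq_len(nrow(traps)), function(i) {
    s <- as.character(sim$genome[[traps$chrom[i]]])
    run <- substring(s, traps$run_start[i], traps$run_end[i])
    if (traps$strand[i] == "-") run <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(run)))
    run
  }, character(1))
  expect_true(all(runbase == strrep("A", 10)))
  expect_false(any(paste(traps$chrom, traps$read_pos) %in%
                     paste(sites$chrom, sites$pos)))
})

test_that("no accidental AATAAA sits in the -40..-1 window of a true site", {
  sim <- simulate_apa_genome(sim_config(n_genes = 50, seed = 5))
  sites <- sim$truth$sites
  win <- vapply(seq_len(nrow(sites)), function(i) {
    s <- as.character(sim$genome[[sites$chrom[i]]])
    p <- sites$pos[i]
    if (sites$strand[i] == "+") substring(s, p - 40, p - 1)
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(s, p + 1, p + 40))))
  }, character(1))
  occ <- gregexpr("AATAAA", win, fixed = TRUE)
  expect_true(all(vapply(occ, function(o) identical(as.integer(o), 20L),
                         logical(1))))
})

test_that("zero jitter and no traps put every read exactly on a true site", {
  cfg <- sim_config(n_genes = 10, cleavage_jitter_sd = 0,
                    internal_priming_rate = 0, depth_per_sample = 500,
                    seed = 7)
  sim <- simulate_apa_genome(cfg)
  reads <- simulate_reads(sim)
  expect_gt(nrow(reads), 0)
  expect_true(all(paste(reads$chrom, reads$pos) %in%
                    paste(sim$truth$sites$chrom, sim$truth$sites$pos)))
})

test_that("every non-artifact read lies within the jitter bound of its site", {
  cfg <- sim_config(n_genes = 20, depth_per_sample = 2000, seed = 8)
  sim <- simulate_apa_genome(cfg)
  reads <- simulate_reads(sim)
  tr <- reads[!reads$artifact, ]
  key <- paste(tr$gene_id, tr$site_rank)
  site_pos <- sim$truth$sites$pos[match(key, paste(sim$truth$sites$gene_id,
                                                   sim$truth$sites$site_rank))]
  expect_true(all(abs(tr$pos - site_pos) <= 3 * cfg$cleavage_jitter_sd))
})

test_that("artifact read count stays within binomial 99% bounds", {
  cfg <- sim_config(n_genes = 20, depth_per_sample = 10000,
                    internal_priming_rate = 0.1, seed = 9)
  sim <- simulate_apa_genome(cfg)
  reads <- simulate_reads(sim)
  n_art <- sum(reads$artifact)
  n_tot <- nrow(reads)
  bounds <- qbinom(c(0.005, 0.995), n_tot, 0.1)
  expect_gte(n_art, bounds[1])
  expect_lte(n_art, bounds[2])
})

test_that("per-gene site usage follows the multinomial marginal (chi-square GOF)", {
  cfg <- sim_config(n_genes = 5, sites_per_gene = c("3" = 1),
                    depth_per_sample = 10000, internal_priming_rate = 0,
                    shortening_fraction = 0, seed = 10)
  sim <- simulate_apa_genome(cfg)
  reads <- simulate_reads(sim)
  one <- reads[reads$sample == "A_1", ]
  for (g in unique(one$gene_id)) {
    gs <- sim$truth$sites[sim$truth$sites$gene_id == g, ]
    obs <- tabulate(one$site_rank[one$gene_id == g], nbins = nrow(gs))
    gof <- suppressWarnings(chisq.test(obs, p = gs$prop_A))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("zero effect size leaves proximal usage equal between conditions", {
  # Monte-Carlo: over replicate simulations the A-vs-B difference in
  # empirical proximal usage stays within sampling error of zero.
  diffs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 10, sites_per_gene = c("2" = 1),
                      depth_per_sample = 5000, internal_priming_rate = 0,
                      shortening_fraction = 0, seed = 100 + s)
    sim <- simulate_apa_genome(cfg)
    reads <- simulate_reads(sim)
    prox <- reads$site_rank == 1L
    condA <- startsWith(reads$sample, "A")
    mean(prox[condA]) - mean(prox[!condA])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("shifted genes raise proximal usage in condition B by the effect size", {
  cfg <- sim_config(n_genes = 40, sites_per_gene = c("2" = 1),
                    shortening_fraction = 0.5, effect_size = 0.3, seed = 12)
  sim <- simulate_apa_genome(cfg)
  st <- sim$truth$sites[sim$truth$sites$site_rank == 1L, ]
  sh <- sim$truth$genes$shifted[match(st$gene_id, sim$truth$genes$gene_id)]
  expect_equal(sum(sh), 20)
  expect_true(all(abs((st$prop_B - st$prop_A)[sh] - 0.3) < 1e-9 |
                    abs(st$prop_B[sh] - 0.95) < 1e-9))
  expect_true(all(st$prop_B[!sh] == st$prop_A[!sh]))
})

test_that("count-level tandem simulator produces valid profiles", {
  out <- simulate_tandem_counts(n_genes = 50, seed = 4)
  expect_length(out$profiles, 50)
  p <- out$profiles[[1]]
  expect_s3_class(p, "tandem_profile")
  expect_equal(p$std_len[length(p$std_len)], 1.0)
  expect_true(all(diff(p$std_len) > 0))
  expect_equal(colnames(p$counts), out$samples)
})
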