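test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_config(9)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$genes, g2$genes)
  d1 <- simulate_damid_counts(cfg, g1)
  d2 <- simulate_damid_counts(cfg, g2)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth$diff_bins, d2$truth$diff_bins)
  r1 <- simulate_rapid_counts(cfg, g1)
  r2 <- simulate_rapid_counts(cfg, g2)
  expect_identical(r1$counts, r2$counts)
  f1 <- emit_fastq(d1$counts[, 1], g1, cfg, decoy_fraction = 0.05, seed = 2)
  f2 <- emit_fastq(d2$counts[, 1], g2, cfg, decoy_fraction = 0.05, seed = 2)
  expect_identical(f1, f2)
})

test_that("GATC density matches the random-sequence expectation", {
  dg <- default_genome()
  L <- sum(as.numeric(dg$genome$gm$chrom_lengths))
  n_sites <- sum(lengths(dg$genome$gm$gatc_sites))
  p <- 1 / 256
  sigma <- sqrt(L * p * (1 - p))
  expect_lt(abs(n_sites - L * p), 3 * sigma)
})

test_that("placed genes are in bounds, disjoint, and respect the minimum gap", {
  dg <- default_genome()
  genes <- dg$genome$genes
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    L <- dg$genome$gm$chrom_lengths[[ch]]
    expect_true(all(g$start >= 0 & g$end <= L & g$start < g$end))
    gaps <- g$start[-1] - g$end[-nrow(g)]
    expect_true(all(gaps >= dg$config$min_intergenic))
  }
  expect_equal(nrow(genes), dg$config$n_genes)
})

test_that("a zero-effect world is exchangeable between fusion and control", {
  cfg <- small_config(6, arm_log2 = 0, frac_diff_bins = 0,
                      baf_depletion_log2 = 0,
                      n_expressed = 0, n_up = 0, n_down = 0)
  genome <- simulate_genome(cfg)
  dam <- simulate_damid_counts(cfg, genome)
  grid <- bin_grid(genome$gm, 10000)
  f <- bin_counts(sample_cols(dam$counts, dam$samples, construct = "fusion",
                              fusion_name = "BAF-1", tissue = "hypodermis"),
                  genome$fragments, grid)
  ctl <- bin_counts(sample_cols(dam$counts, dam$samples,
                                construct = "dam_control",
                                tissue = "hypodermis"),
                    genome$fragments, grid)
  e <- nb_enrichment_test(f, ctl)
  expect_lte(mean(e$qval < 0.05), 0.05)
})

test_that("the planted arm effect is recovered from the normalized track", {
  dg <- default_genome()
  dam <- simulate_damid_counts(dg$config, dg$genome)
  grid <- bin_grid(dg$genome$gm, 10000)
  f <- bin_counts(sample_cols(dam$counts, dam$samples, construct = "fusion",
                              fusion_name = "BAF-1", tissue = "intestine"),
                  dg$genome$fragments, grid)
  ctl <- bin_counts(sample_cols(dam$counts, dam$samples,
                                construct = "dam_control",
                                tissue = "intestine"),
                    dg$genome$fragments, grid)
  track <- normalize_ratio(f, ctl)
  mid <- (grid$start + grid$end) %/% 2
  lab <- classify_arm_center(grid$chrom, mid, dg$genome$gm$borders,
                             known_chroms = dg$genome$gm$chrom_names)
  gap <- mean(track[lab == "arm"]) - mean(track[lab == "center"])
  expect_lt(abs(gap - dg$config$arm_log2), 0.1)
})

test_that("per-bin sampling variance scales inversely with depth (Poisson limit)", {
  # with NB dispersion the spread has a depth-independent floor, so the
  # halving law is checked at dispersion zero
  cfg1 <- small_config(8, nb_dispersion = 0, reads_per_replicate = 2e5,
                       arm_log2 = 0, frac_diff_bins = 0,
                       baf_depletion_log2 = 0)
  cfg2 <- small_config(8, nb_dispersion = 0, reads_per_replicate = 8e5,
                       arm_log2 = 0, frac_diff_bins = 0,
                       baf_depletion_log2 = 0)
  genome <- simulate_genome(cfg1)
  v1 <- v2 <- NULL
  for (cfg in list(cfg1, cfg2)) {
    dam <- simulate_damid_counts(cfg, genome)
    grid <- bin_grid(genome$gm, 10000)
    f <- bin_counts(sample_cols(dam$counts, dam$samples,
                                construct = "fusion",
                                fusion_name = "BAF-1",
                                tissue = "hypodermis"),
                    genome$fragments, grid)
    ctl <- bin_counts(sample_cols(dam$counts, dam$samples,
                                  construct = "dam_control",
                                  tissue = "hypodermis"),
                      genome$fragments, grid)
    v <- var(normalize_ratio(f, ctl))
    if (is.null(v1)) v1 <- v else v2 <- v
  }
  # 4x the reads -> about a quarter of the variance
  expect_lt(abs(v1 / v2 - 4) / 4, 0.35)
})

test_that("emitted FASTQ reads round trip to the exact input counts", {
  cfg <- small_config(5)
  genome <- simulate_genome(cfg)
  dam <- simulate_damid_counts(cfg, genome)
  cnt <- dam$counts[, 1]
  reads <- emit_fastq(cnt, genome, cfg)
  expect_equal(nrow(reads), sum(cnt))
  expect_true(all(startsWith(reads$seq, "CGCGGCCGAG")))
  res <- filter_reads(reads, read_filter_params(), genome$gm,
                      genome$sequences, genome$fragments,
                      read_length = cfg$read_length)
  expect_equal(res$n_retained, sum(cnt))
  expect_identical(as.integer(count_fragments(res$assignments,
                                              genome$fragments)),
                   as.integer(cnt))
})

test_that("decoy reads are discarded by reason and do not disturb counts", {
  cfg <- small_config(5)
  genome <- simulate_genome(cfg)
  dam <- simulate_damid_counts(cfg, genome)
  cnt <- dam$counts[, 2]
  reads <- emit_fastq(cnt, genome, cfg, decoy_fraction = 0.1, seed = 4)
  res <- filter_reads(reads, read_filter_params(), genome$gm,
                      genome$sequences, genome$fragments,
                      read_length = cfg$read_length)
  expect_equal(res$n_retained, sum(cnt))
  expect_equal(res$n_retained / nrow(reads), 0.9, tolerance = 0.01)
  expect_gt(res$discarded[["no_adapter"]], 0)
  expect_gt(res$discarded[["no_gatc_anchor"]], 0)
  expect_identical(as.integer(count_fragments(res$assignments,
                                              genome$fragments)),
                   as.integer(cnt))
})

test_that("swapping genotype labels swaps the deregulation ground truth", {
  # the planted up set is 'on in mutant only', down 'on in wild type
  # only': relabelling genotypes exchanges their roles by construction
  cfg <- small_config(10)
  genome <- simulate_genome(cfg)
  tr <- simulate_truth(cfg, genome)
  for (t in cfg$tissues) {
    expect_length(intersect(tr$up[[t]], tr$expressed[[t]]), 0)
    expect_true(all(tr$down[[t]] %in% tr$expressed[[t]]))
    mut_expressed <- union(setdiff(tr$expressed[[t]], tr$down[[t]]),
                           tr$up[[t]])
    # relabel: wt' = mut => up' (on in mut', off in wt') = old down set
    expect_setequal(setdiff(tr$expressed[[t]], mut_expressed),
                    tr$down[[t]])
    expect_setequal(setdiff(mut_expressed, tr$expressed[[t]]),
                    tr$up[[t]])
  }
})
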