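toy_occupancy_world <- function() {
  cl <- c(chrI = 4000L)
  gm <- genome_model(chrom_lengths = cl,
                     gatc_sites = list(chrI = c(1000L, 2000L, 3000L)),
                     borders = NULL)
  fr <- gatc_fragments(gm)
  genes <- gene_intervals(
    data.frame(gene_id = c("A", "B"), chrom = "chrI",
               start = c(0L, 2100L), end = c(1900L, 4000L)), cl, 0)
  list(gm = gm, fr = fr, genes = genes)
}

test_that("gene_occupancy is zero for identical samples and exact on a toy", {
  w <- toy_occupancy_world()
  m <- cbind(c(30L, 20L, 10L, 40L), c(25L, 25L, 15L, 35L))
  occ0 <- gene_occupancy(m, m, w$fr, w$genes)
  expect_equal(unname(occ0$average), c(0, 0))
  # 10x Pol II excess on gene A with a flat control, hand arithmetic:
  # gene A = fragments 1-2, gene B = fragments 3-4 (by midpoint)
  rpb6 <- cbind(c(500L, 500L, 50L, 50L))
  gfp <- cbind(c(50L, 50L, 50L, 50L))
  occ <- gene_occupancy(rpb6, gfp, w$fr, w$genes)
  expect_equal(unname(occ$average["A"]),
               log2((1001 / 1102) / (101 / 202)), tolerance = 1e-12)
  # occupancy difference between the genes recovers the planted 10x
  expect_equal(unname(occ$average["A"] - occ$average["B"]),
               log2(1001 / 101), tolerance = 1e-12)
  expect_error(gene_occupancy(cbind(1:4), m, w$fr, w$genes),
               "replicate count mismatch")
})

test_that("expressed calling controls false positives on a null world", {
  cfg <- small_config(3, n_expressed = 0, n_up = 0, n_down = 0)
  genome <- simulate_genome(cfg)
  rap <- simulate_rapid_counts(cfg, genome)
  ge <- gene_intervals(genome$genes, genome$gm$chrom_lengths, 500)
  tab <- rapid_gene_table(
    sample_cols(rap$counts, rap$samples, construct = "rpb6",
                genotype = "wt", tissue = "hypodermis"),
    sample_cols(rap$counts, rap$samples, construct = "dam_control",
                genotype = "wt", tissue = "hypodermis"),
    genome$fragments, ge, B = 400, seed = 6)
  expect_lte(length(call_expressed(tab)), 0.05 * nrow(tab))
  # permutation p-values are roughly uniform under the null
  expect_lte(mean(tab$p_value < 0.1), 1.5 * 0.1)
})

test_that("expressed calling recovers planted genes; top gene always called", {
  cfg <- small_config(4)
  genome <- simulate_genome(cfg)
  rap <- simulate_rapid_counts(cfg, genome)
  ge <- gene_intervals(genome$genes, genome$gm$chrom_lengths, 500)
  tab <- rapid_gene_table(
    sample_cols(rap$counts, rap$samples, construct = "rpb6",
                genotype = "wt", tissue = "hypodermis"),
    sample_cols(rap$counts, rap$samples, construct = "dam_control",
                genotype = "wt", tissue = "hypodermis"),
    genome$fragments, ge, B = 400, seed = 6)
  called <- call_expressed(tab)
  planted <- rap$truth$expressed$hypodermis
  expect_gte(mean(planted %in% called), 0.9)
  expect_lte(sum(!(called %in% planted)), 0.1 * length(planted))
  # monotonicity: the maximum-occupancy gene is always called
  expect_true(tab$gene_id[which.max(tab$average)] %in% called)
  expect_warning(rapid_gene_table(
    cbind(c(1L, 2L, 3L), 1L), cbind(c(1L, 1L, 1L), 1L),
    data.frame(chrom = "chrI", start = c(0L, 10L, 20L),
               end = c(10L, 20L, 30L), gatc_anchored = TRUE,
               fragment_id = 1:3),
    data.frame(gene_id = "g", chrom = "chrI", start = 0L, end = 30L),
    B = 50, seed = 1), "B < 100")
})

fake_rapid_table <- function(ids, rep1, rep2) {
  data.table::data.table(gene_id = ids, occupancy_rep1 = rep1,
                         occupancy_rep2 = rep2,
                         average = (rep1 + rep2) / 2,
                         p_value = 0.01, q_value = 0.01,
                         expressed = TRUE)
}

test_that("call_deregulated needs every replicate past the threshold", {
  ids <- c("g1", "g2", "g3", "g4")
  wt <- fake_rapid_table(ids, rep(0, 4), rep(0, 4))
  mut <- fake_rapid_table(ids,
                          c(1.2, 1.2, -1.5, 1.01),
                          c(1.4, 0.3, -1.1, 0.99))
  d <- call_deregulated(wt, mut, expressed_union = ids)
  expect_equal(d$direction, c("up", "none", "down", "none"))
  # strictness at the boundary: average must also exceed the threshold
  mut2 <- fake_rapid_table(ids, rep(1.0, 4), rep(1.0, 4))
  d2 <- call_deregulated(wt, mut2, expressed_union = ids)
  expect_true(all(d2$direction == "none"))
  # genes outside the expressed union are never called
  d3 <- call_deregulated(wt, mut, expressed_union = c("g3"))
  expect_equal(d3$direction, c("none", "none", "down", "none"))
  expect_error(
    call_deregulated(wt, mut[, -"occupancy_rep2"], expressed_union = ids),
    "replicate count mismatch")
})

test_that("call_deregulated is antisymmetric under genotype swap", {
  set.seed(77)
  ids <- sprintf("g%02d", 1:40)
  wt <- fake_rapid_table(ids, rnorm(40), rnorm(40))
  mut <- fake_rapid_table(ids, rnorm(40, sd = 2), rnorm(40, sd = 2))
  fwd <- call_deregulated(wt, mut, expressed_union = ids)
  rev <- call_deregulated(mut, wt, expressed_union = ids)
  expect_equal(fwd$gene_id[fwd$direction == "up"],
               rev$gene_id[rev$direction == "down"])
  expect_equal(fwd$gene_id[fwd$direction == "down"],
               rev$gene_id[rev$direction == "up"])
  expect_equal(fwd$average_delta, -rev$average_delta)
})

test_that("crosslink pairs deregulated genes with binding values", {
  ids <- sprintf("g%02d", 1:20)
  dereg <- data.table::data.table(
    gene_id = ids,
    direction = rep(c("up", "down", "none", "none"), 5))
  tr <- stats::setNames(rnorm(20, sd = 0.3), ids)
  # identical tracks: zero differences, t = 0, p = 1
  r0 <- crosslink_deregulated_to_binding(dereg, tr, tr)
  expect_equal(r0$tests$p_value, c(1, 1))
  expect_equal(r0$tests$t, c(0, 0))
  # a constant +0.5 shift has mean difference 0.5 and a degenerate p
  r1 <- crosslink_deregulated_to_binding(dereg, tr, tr + 0.5)
  expect_equal(r1$tests$mean_diff, c(0.5, 0.5))
  expect_true(all(r1$tests$p_value < 0.01))
  # noisy shift matches the closed-form paired t-test
  set.seed(3)
  noise <- rnorm(20, sd = 0.1)
  r2 <- crosslink_deregulated_to_binding(dereg, tr, tr + 0.4 + noise,
                                         exclude_outliers = FALSE)
  d_up <- (0.4 + noise)[dereg$direction == "up"]
  t_manual <- mean(d_up) / (sd(d_up) / sqrt(length(d_up)))
  expect_equal(r2$tests$t[r2$tests$direction == "up"], t_manual,
               tolerance = 1e-9)
  # disjoint gene universes: empty join, tests skipped
  r3 <- crosslink_deregulated_to_binding(
    dereg, stats::setNames(rnorm(3), c("x1", "x2", "x3")),
    stats::setNames(rnorm(3), c("x1", "x2", "x3")))
  expect_equal(nrow(r3$table), 0L)
  expect_true(all(is.na(r3$tests$p_value)))
})
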