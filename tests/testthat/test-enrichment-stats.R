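test_that("benjamini_hochberg matches hand arithmetic and edge cases", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(-0.1)), "\\[0, 1\\]")
})

test_that("benjamini_hochberg equals the brute-force step-up oracle", {
  set.seed(88)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    q <- benjamini_hochberg(p)
    expect_identical(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15)) # monotone with p
  }
})

test_that("median-of-ratios size factors recover depth differences", {
  set.seed(4)
  base <- rpois(500, 100)
  m <- cbind(base, base * 3L, base * 10L)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf / sf[1]), c(1, 3, 10), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("nb_enrichment_test finds nothing when fusion equals control", {
  set.seed(12)
  m <- matrix(rnbinom(900, mu = 80, size = 10), ncol = 3)
  e <- nb_enrichment_test(m, m)
  expect_equal(sum(e$enriched), 0L)
  expect_equal(e$log2fc, rep(0, 300), tolerance = 1e-8)
})

test_that("nb_enrichment_test handles degenerate rows and bad input", {
  f <- matrix(rpois(30, 50), ncol = 3)
  c_ <- matrix(rpois(30, 50), ncol = 3)
  f[1, ] <- 0L; c_[1, ] <- 0L
  e <- nb_enrichment_test(f, c_)
  expect_equal(e$pval[1], 1)
  expect_equal(e$log2fc[1], 0)
  expect_error(nb_enrichment_test(matrix(1:6, ncol = 2),
                                  matrix(1:8, ncol = 2)), "mismatch")
  # single replicate per side: Poisson fallback, flagged
  e1 <- nb_enrichment_test(cbind(rpois(100, 50)), cbind(rpois(100, 50)))
  expect_true(attr(e1, "poisson_fallback"))
})

test_that("nb_enrichment_test controls type-I error on null simulations", {
  frac_p <- frac_q <- numeric(3)
  for (s in 1:3) {
    set.seed(s)
    f <- matrix(rnbinom(3000, mu = 100, size = 10), ncol = 3)
    c_ <- matrix(rnbinom(3000, mu = 100, size = 10), ncol = 3)
    e <- nb_enrichment_test(f, c_)
    frac_p[s] <- mean(e$pval < 0.05)
    frac_q[s] <- mean(e$qval < 0.05)
  }
  expect_true(all(frac_p <= 1.5 * 0.05))
  expect_true(all(frac_q <= 1.5 * 0.05))
})

test_that("nb_enrichment_test recovers strongly planted bins", {
  set.seed(42)
  n <- 1000
  mu_c <- rep(100, n)
  mu_f <- mu_c
  mu_f[1:50] <- mu_f[1:50] * 8
  f <- matrix(rnbinom(3 * n, mu = mu_f, size = 20), ncol = 3)
  c_ <- matrix(rnbinom(3 * n, mu = mu_c, size = 20), ncol = 3)
  e <- nb_enrichment_test(f, c_)
  expect_gte(sum(e$enriched[1:50]), 45)
  expect_lte(sum(e$enriched[-(1:50)]), 0.05 * 50)
})

test_that("differential_accessibility reports both directions and percents", {
  set.seed(9)
  m <- matrix(rnbinom(1800, mu = 120, size = 10), ncol = 3)
  acc0 <- differential_accessibility(m, m, bin_size = 2000,
                                     genome_length = 600 * 2000)
  expect_equal(unname(acc0$n_bins), c(0L, 0L))
  # planted 2% of bins with 4x tissue-1 excess at ~1e6 reads/replicate
  n <- 3000
  mu <- rep(1e6 / n, n)
  idx <- seq_len(60)
  mu1 <- mu; mu1[idx] <- mu1[idx] * 4
  t1 <- matrix(rnbinom(3 * n, mu = mu1, size = 10), ncol = 3)
  t2 <- matrix(rnbinom(3 * n, mu = mu, size = 10), ncol = 3)
  acc <- differential_accessibility(t1, t2, bin_size = 2000,
                                    genome_length = n * 2000)
  expect_gte(mean(acc$up_in_tissue1$enriched[idx]), 0.9)
  expect_equal(unname(acc$percent_of_genome["tissue1"]),
               100 * unname(acc$n_bins["tissue1"]) * 2000 / (n * 2000))
})

test_that("differential_association applies the strict delta cut", {
  n <- 10
  enr <- data.table::data.table(qval = rep(0.001, n), log2fc = 1,
                                enriched = rep(TRUE, n))
  trA <- rep(0, n); trB <- rep(0, n)
  # identical tracks: both sets empty regardless of enrichment
  r0 <- differential_association(enr, enr, trA, trB)
  expect_equal(unname(r0$n), c(0L, 0L))
  # delta exactly 0.58 excluded, 1.0 included
  trA2 <- trA; trA2[1] <- 0.58; trA2[2] <- 1.0
  r <- differential_association(enr, enr, trA2, trB)
  expect_false(r$a_preferential[1])
  expect_true(r$a_preferential[2])
  # output sets are disjoint on arbitrary input
  set.seed(5)
  trR <- rnorm(n); trS <- rnorm(n)
  enr2 <- data.table::data.table(qval = runif(n), log2fc = rnorm(n),
                                 enriched = sample(c(TRUE, FALSE), n, TRUE))
  rr <- differential_association(enr2, enr2, trR, trS)
  expect_equal(sum(rr$a_preferential & rr$b_preferential), 0L)
  expect_error(differential_association(enr, enr, trA, rep(0, n + 1)),
               "grid mismatch")
})

test_that("differential_association reports arm bias against genome fraction", {
  n <- 100
  labels <- rep(c("arm", "center"), each = 50)
  enr <- data.table::data.table(qval = 0.001, log2fc = 1,
                                enriched = rep(TRUE, n))
  trA <- rep(0, n); trA[1:20] <- 2  # 20 arm bins preferential
  r <- differential_association(enr, enr, trA, rep(0, n), labels = labels)
  expect_equal(r$a_arm$n, 20L)
  expect_equal(r$a_arm$percent_arm, 100)
  expect_lt(r$a_arm$p_value, 0.01)
  expect_equal(r$genome_arm_fraction, 0.5)
})

test_that("arm_center_compare summarises groups and tests pairs", {
  set.seed(20)
  v <- rnorm(300)
  lab <- rep(c("arm", "center"), 150)
  r <- arm_center_compare(v, lab)
  expect_equal(nrow(r$summary), 2L)
  expect_equal(nrow(r$pairs), 1L)
  # same multiset split at random: no systematic difference
  expect_gt(r$pairs$p_value, 0.001)
  # a unit shift is detected, and medians differ by 1
  r2 <- arm_center_compare(c(v, v + 1), rep(c("arm", "center"), each = 300))
  expect_lt(r2$pairs$p_value, 0.01)
  expect_equal(r2$summary$median[r2$summary$group == "center"] -
                 r2$summary$median[r2$summary$group == "arm"], 1,
               tolerance = 1e-9)
  # single group: empty pair table
  r3 <- arm_center_compare(v, rep("arm", 300))
  expect_equal(nrow(r3$pairs), 0L)
  # not_applicable values are dropped
  r4 <- arm_center_compare(c(v, 99), c(lab, "not_applicable"))
  expect_equal(sum(r4$summary$n), 300)
})

test_that("arm_center_compare agrees with exact rank-sum enumeration at small n", {
  # exact oracle: enumerate all splits of the pooled values
  exact_ranksum_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    idx <- utils::combn(length(pooled), n)
    w_obs <- sum(rank(pooled)[seq_len(n)])
    ws <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  }
  set.seed(14)
  x <- rnorm(5); y <- rnorm(6) + 0.5
  r <- arm_center_compare(c(x, y), rep(c("a", "b"), c(5, 6)))
  expect_equal(r$pairs$p_value, exact_ranksum_p(x, y), tolerance = 1e-9)
})
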