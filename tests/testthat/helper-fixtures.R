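# Shared fixtures, built in code. The desk-scale default study (6 Mb) is
# cached per session because several files exercise it; the small
# configuration keeps module-level simulations fast.

.fixture_env <- new.env(parent = emptyenv())

# full default synthetic study (used by acceptance + pipeline tests)
default_genome <- function(seed = 1) {
  key <- paste0("genome_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- simulation_config(seed = seed)
    .fixture_env[[key]] <- list(config = cfg, genome = simulate_genome(cfg))
  }
  .fixture_env[[key]]
}

# small world: 6 x 150 kb chromosomes, 150 genes, light depth
small_config <- function(seed, ...) {
  defaults <- list(
    chrom_lengths = stats::setNames(
      rep(150000, 6), c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")),
    n_genes = 150,
    n_expressed = 30, n_up = 6, n_down = 5,
    reads_per_replicate = 2e5
  )
  do.call(simulation_config,
          c(list(seed = seed), utils::modifyList(defaults, list(...))))
}

small_genome <- function(seed = 2) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- small_config(seed)
    .fixture_env[[key]] <- list(config = cfg, genome = simulate_genome(cfg))
  }
  .fixture_env[[key]]
}

# column selector for simulated sample sheets
sample_cols <- function(counts, samples, ...) {
  filt <- list(...)
  sel <- rep(TRUE, nrow(samples))
  for (nm in names(filt)) sel <- sel & samples[[nm]] == filt[[nm]]
  counts[, samples$sample_id[sel], drop = FALSE]
}

# independent brute-force BH step-up oracle (kept deliberately naive)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[o][i] / i)
    q_sorted[i] <- prev
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
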