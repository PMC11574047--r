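# Synthetic study generator: a toy genome with discovered (not planted)
# GATC sites, a gene annotation, and seeded NB count data carrying the
# statistical structure the analysis assumes -- arm-biased fusion
# binding, planted genotype-differential bins, planted expressed and
# deregulated genes -- plus FASTQ emission for round-trip tests.

#' Configuration of the synthetic study
#'
#' Defaults emulate the real experimental design at desk scale: a 6 Mb
#' toy genome (5 autosomes + chrX, 1 Mb each, arm/center borders at 1/3
#' and 2/3), ~4 GATC sites per kb (the random-sequence expectation of a
#' 4-mer), 2000 genes of ~2 kb, DamID with 2 tissues x {fusion wild-type,
#' fusion mutant, Dam-only} x 3 replicates, RAPID with 2 tissues x 2
#' genotypes x {Dam::RPB-6, GFP::Dam} x 2 replicates.
#'
#' @param seed root RNG seed (mandatory); every stage derives a named
#'   substream from it
#' @param chrom_lengths named vector of toy chromosome lengths
#' @param n_genes number of non-overlapping genes to place
#' @param gene_mean_length mean gene length (lognormal) in bp
#' @param arm_log2 fusion log2 enrichment on autosome arms (default 1)
#' @param frac_diff_bins fraction of autosomal bins with a genotype-
#'   specific effect (default 0.02)
#' @param diff_log2 log2 effect of a differential bin (default 1)
#' @param diff_bin_size grid on which differential bins are planted
#'   (default 10 kb, the resolution of the differential analysis)
#' @param n_expressed expressed genes per tissue (default 200)
#' @param n_up,n_down deregulated genes per tissue (defaults 36 / 26,
#'   the hypodermis-scale design)
#' @param expr_log2 RPB-6 occupancy effect of an expressed gene
#'   (default 2)
#' @param dereg_log2 genotype effect of a deregulated gene (default 2)
#' @param baf_depletion_log2 depletion of fusion signal over expressed
#'   gene bodies (default 1), reproducing the expressed-genes-avoid-BAF
#'   ordering
#' @param nb_dispersion NB dispersion alpha at the fragment level
#'   (variance mu + alpha mu^2; default 0.1)
#' @param reads_per_replicate expected retained reads per sample
#'   (default 1e6, the low end of the real libraries)
#' @param reps_damid,reps_rapid replicates per arm (3 and 2)
#' @param min_intergenic minimum gap between placed genes (default
#'   750 bp). With the 500 bp methylation spread / quantification
#'   extension, two adjacent measured domains can then share at most
#'   250 bp of fragments, so spill from a neighbouring planted gene can
#'   never mimic a deregulation effect
#' @param min_mappable_fragment fragments shorter than this receive no
#'   reads (default 25 bp; mimics the amplicon-size lower bound and keeps
#'   read-to-fragment assignment unambiguous)
#' @param read_length genomic part of an emitted read (default 50 bp)
#' @param tissues tissue labels
#' @return a `SimulationConfig` list
#' @export
simulation_config <- function(seed,
                              chrom_lengths = stats::setNames(
                                rep(1e6, 6),
                                c("chrI", "chrII", "chrIII", "chrIV",
                                  "chrV", "chrX")),
                              n_genes = 2000,
                              gene_mean_length = 2000,
                              arm_log2 = 1.0,
                              frac_diff_bins = 0.02,
                              diff_log2 = 1.0,
                              diff_bin_size = 10000,
                              n_expressed = 200,
                              n_up = 36, n_down = 26,
                              expr_log2 = 2.0,
                              dereg_log2 = 2.0,
                              baf_depletion_log2 = 1.0,
                              nb_dispersion = 0.1,
                              reads_per_replicate = 1e6,
                              reps_damid = 3, reps_rapid = 2,
                              min_intergenic = 750,
                              min_mappable_fragment = 25,
                              read_length = 50,
                              tissues = c("hypodermis", "intestine")) {
  stopifnot(!missing(seed), frac_diff_bins >= 0, frac_diff_bins <= 1,
            is.finite(arm_log2), is.finite(diff_log2),
            nb_dispersion >= 0, reads_per_replicate > 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate the toy genome, GATC landscape, and gene annotation
#'
#' Chromosome sequences are i.i.d. uniform nucleotides; GATC sites are
#' discovered by scanning (never planted). Genes are non-overlapping,
#' with lognormal lengths, placed by distributing the free space between
#' them at random.
#'
#' @param config a [simulation_config()]
#' @return list with `sequences` (named character), `gm` (`GenomeModel`
#'   with borders at 1/3 and 2/3 of each autosome), `genes`
#'   (data.table gene_id, chrom, start, end, strand), and `fragments`
#' @export
simulate_genome <- function(config) {
  set.seed(substream_seed(config$seed, 1L))
  chroms <- names(config$chrom_lengths)
  sequences <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_lengths[[ch]],
                 replace = TRUE), collapse = "")
  }, character(1))
  autosomes <- setdiff(chroms, c("chrX", "chrM"))
  borders <- data.frame(
    chrom = autosomes,
    b1 = floor(config$chrom_lengths[autosomes] / 3),
    b2 = floor(2 * config$chrom_lengths[autosomes] / 3)
  )
  gm <- genome_model(sequences, borders = borders)
  # allocate genes to chromosomes proportional to length (deterministic
  # split so packing stays feasible)
  cum <- round(cumsum(config$chrom_lengths / sum(config$chrom_lengths)) *
                 config$n_genes)
  n_per <- diff(c(0, cum))
  genes <- data.table::rbindlist(lapply(seq_along(chroms), function(i) {
    n <- n_per[i]
    if (n == 0) return(NULL)
    L <- config$chrom_lengths[[i]]
    sdlog <- 0.5
    len <- NULL
    for (try in 1:20) {
      len <- round(stats::rlnorm(n, log(config$gene_mean_length) -
                                   sdlog^2 / 2, sdlog))
      len <- pmin(pmax(len, 200), 20000)
      if (sum(len) + (n + 1) * config$min_intergenic <= 0.97 * L) break
      len <- NULL
    }
    if (is.null(len))
      stop("cannot place genes without overlap; lower n_genes")
    free <- L - sum(len) - (n + 1) * config$min_intergenic
    w <- stats::rexp(n + 1)
    gaps <- config$min_intergenic + floor(free * w / sum(w))
    start <- cumsum(c(gaps[1], len[-n] + gaps[2:n]))
    data.table::data.table(
      chrom = chroms[i],
      start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  }))
  data.table::setorder(genes, chrom, start)
  genes[, gene_id := sprintf("gene%04d", seq_len(.N))]
  data.table::setcolorder(genes, c("gene_id", "chrom", "start", "end",
                                   "strand"))
  list(sequences = sequences, gm = gm, genes = genes[],
       fragments = gatc_fragments(gm))
}

#' Plant the ground-truth signal structure
#'
#' Chooses, deterministically from the seed: the genotype-differential
#' bins per tissue (in the first tissue the mutant-preferential bins are
#' drawn from chromosome centers and the wild-type-preferential ones
#' from arms, mirroring the shifted-binding observation; in the second
#' tissue both directions are drawn uniformly), the expressed gene set
#' per tissue, and disjoint up/down deregulated subsets of it.
#'
#' @param config a [simulation_config()]
#' @param genome a [simulate_genome()] result
#' @return list with `diff_bins` (per tissue: data.table bin_id,
#'   direction in {wt, mut}), `expressed` and `up`/`down` gene ids per
#'   tissue, plus the `grid` used
#' @export
simulate_truth <- function(config, genome) {
  set.seed(substream_seed(config$seed, 2L))
  grid <- bin_grid(genome$gm, config$diff_bin_size)
  mid <- (grid$start + grid$end) %/% 2
  lab <- classify_arm_center(grid$chrom, mid, genome$gm$borders,
                             known_chroms = genome$gm$chrom_names)
  auto <- which(lab != "not_applicable")
  n_diff <- round(config$frac_diff_bins * length(auto))
  n_mut <- ceiling(n_diff / 2); n_wt <- n_diff - n_mut
  diff_bins <- list()
  for (ti in seq_along(config$tissues)) {
    if (ti == 1) {
      mut_pool <- auto[lab[auto] == "center"]
      wt_pool <- auto[lab[auto] == "arm"]
    } else {
      mut_pool <- auto; wt_pool <- auto
    }
    mut_bins <- sample(mut_pool, n_mut)
    wt_bins <- sample(setdiff(wt_pool, mut_bins), n_wt)
    diff_bins[[config$tissues[ti]]] <- data.table::data.table(
      bin_id = c(wt_bins, mut_bins),
      direction = rep(c("wt", "mut"), c(n_wt, n_mut))
    )
  }
  # expressed = wild-type expressed set; up-genes are off in wild type
  # and on in the mutant (delta +dereg_log2), down-genes the reverse
  expressed <- list(); up <- list(); down <- list()
  for (t in config$tissues) {
    ex <- sort(sample(genome$genes$gene_id, config$n_expressed))
    up[[t]] <- sort(sample(setdiff(genome$genes$gene_id, ex),
                           config$n_up))
    down[[t]] <- sort(sample(ex, config$n_down))
    expressed[[t]] <- ex
  }
  list(grid = grid, bin_labels = lab, diff_bins = diff_bins,
       expressed = expressed, up = up, down = down)
}

# Per-fragment base sampling weights: proportional to fragment length,
# zero for fragments without a GATC anchor or below the mappable minimum.
fragment_weights <- function(fragments, config) {
  len <- fragments$end - fragments$start
  w <- as.numeric(len)
  w[!fragments$gatc_anchored] <- 0
  w[len < config$min_mappable_fragment] <- 0
  w
}

# Midpoint membership of fragments in a set of gene methylation
# domains. Dam methylation spreads past transcript ends, which is why
# gene-level quantification extends intervals by 500 bp; planted
# per-gene effects cover the same +/-500 bp domain so a planted
# occupancy effect is what the quantification measures. The generator's
# minimum intergenic gap keeps the spill into a neighbouring gene's
# measured domain small.
fragments_in_genes <- function(fragments, genes, gene_ids,
                               chrom_lengths = NULL, extension = 500) {
  g <- genes[genes$gene_id %in% gene_ids, ]
  if (!is.null(chrom_lengths) && extension > 0 && nrow(g))
    g <- gene_intervals(g, chrom_lengths, extension)
  mid <- (fragments$start + fragments$end) %/% 2L
  fr <- data.table::data.table(chrom = fragments$chrom, start = mid,
                               end = mid + 1L,
                               frag_row = seq_len(nrow(fragments)))
  ge <- data.table::data.table(chrom = g$chrom,
                               start = as.integer(g$start),
                               end = as.integer(g$end))
  if (!nrow(ge)) return(logical(nrow(fragments)))
  data.table::setkey(ge, chrom, start, end)
  ov <- data.table::foverlaps(fr, ge, type = "within", nomatch = NULL)
  out <- logical(nrow(fragments))
  out[unique(ov$frag_row)] <- TRUE
  out
}

nb_draw <- function(mu, alpha) {
  if (alpha <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

#' Simulate DamID fragment counts for the binding study
#'
#' Samples: {fusion wild-type, fusion mutant, Dam-only control} x tissues
#' x `reps_damid` replicates. The Dam-only control is flat (length-
#' proportional); fusions gain `arm_log2` on autosome arms, lose
#' `baf_depletion_log2` over expressed gene bodies, and the planted
#' differential bins boost one genotype by `diff_log2`. Counts are NB
#' with one global dispersion, scaled to `reads_per_replicate`.
#'
#' @param config a [simulation_config()]
#' @param genome a [simulate_genome()] result
#' @param truth a [simulate_truth()] result (built if NULL)
#' @return list with `counts` (fragments x samples matrix), `samples`
#'   (data.table sample_id, construct, fusion_name, genotype, tissue,
#'   replicate), and `truth`
#' @export
simulate_damid_counts <- function(config, genome, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config, genome)
  set.seed(substream_seed(config$seed, 3L))
  fr <- genome$fragments
  base_w <- fragment_weights(fr, config)
  mid <- (fr$start + fr$end) %/% 2
  lab <- classify_arm_center(fr$chrom, mid, genome$gm$borders,
                             known_chroms = genome$gm$chrom_names)
  arm_frag <- lab == "arm"
  bin_size <- attr(truth$grid, "bin_size")
  first_bin <- truth$grid[, .(first = min(bin_id)), by = chrom]
  off <- stats::setNames(first_bin$first, first_bin$chrom)
  frag_bin <- off[fr$chrom] + mid %/% bin_size
  samples <- data.table::CJ(tissue = config$tissues,
                            fusion_name = c("BAF-1", "BAF-1(G12T)", "none"),
                            replicate = seq_len(config$reps_damid),
                            sorted = FALSE)
  samples[, construct := ifelse(fusion_name == "none", "dam_control",
                                "fusion")]
  samples[, sample_id := paste0(
    ifelse(construct == "fusion", paste0("Dam_", gsub("[()]", "", fusion_name)),
           "GFPDam"), "_", tissue, "_rep", replicate)]
  counts <- matrix(0L, nrow = nrow(fr), ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j]
    w <- base_w
    if (s$construct == "fusion") {
      w[arm_frag] <- w[arm_frag] * 2^config$arm_log2
      depl <- fragments_in_genes(fr, genome$genes,
                                 truth$expressed[[s$tissue]],
                                 genome$gm$chrom_lengths)
      w[depl] <- w[depl] * 2^(-config$baf_depletion_log2)
      db <- truth$diff_bins[[s$tissue]]
      boost_dir <- if (s$fusion_name == "BAF-1") "wt" else "mut"
      boosted <- frag_bin %in% db$bin_id[db$direction == boost_dir]
      w[boosted] <- w[boosted] * 2^config$diff_log2
    }
    mu <- w / sum(w) * config$reads_per_replicate
    counts[, j] <- nb_draw(mu, config$nb_dispersion)
  }
  list(counts = counts, samples = samples[], truth = truth)
}

#' Simulate RAPID fragment counts for the expression study
#'
#' Samples: {Dam::RPB-6, GFP::Dam} x genotypes {wt, mut} x tissues x
#' `reps_rapid` replicates. RPB-6 signal over the genotype's expressed
#' methylation domains is boosted by `expr_log2`. The mutant's expressed
#' set is the wild-type set minus the planted down-genes (on -> off)
#' plus the planted up-genes (off -> on, boosted by `dereg_log2`), so
#' both directions carry |delta log2| = `dereg_log2` without stacking
#' effects.
#'
#' @inheritParams simulate_damid_counts
#' @return list with `counts`, `samples`, `truth`
#' @export
simulate_rapid_counts <- function(config, genome, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config, genome)
  set.seed(substream_seed(config$seed, 4L))
  fr <- genome$fragments
  base_w <- fragment_weights(fr, config)
  samples <- data.table::CJ(tissue = config$tissues,
                            genotype = c("wt", "mut"),
                            construct = c("rpb6", "dam_control"),
                            replicate = seq_len(config$reps_rapid),
                            sorted = FALSE)
  samples[, sample_id := paste0(
    ifelse(construct == "rpb6", "DamRPB6", "GFPDam"),
    "_", genotype, "_", tissue, "_rep", replicate)]
  counts <- matrix(0L, nrow = nrow(fr), ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  in_genes <- list()
  for (t in config$tissues) {
    cl <- genome$gm$chrom_lengths
    in_genes[[t]] <- list(
      expressed_wt = fragments_in_genes(
        fr, genome$genes, truth$expressed[[t]], cl),
      expressed_mut = fragments_in_genes(
        fr, genome$genes,
        setdiff(truth$expressed[[t]], truth$down[[t]]), cl),
      up = fragments_in_genes(fr, genome$genes, truth$up[[t]], cl)
    )
  }
  for (j in seq_len(nrow(samples))) {
    s <- samples[j]
    w <- base_w
    if (s$construct == "rpb6") {
      m <- in_genes[[s$tissue]]
      if (s$genotype == "wt") {
        w[m$expressed_wt] <- w[m$expressed_wt] * 2^config$expr_log2
      } else {
        w[m$expressed_mut] <- w[m$expressed_mut] * 2^config$expr_log2
        w[m$up] <- w[m$up] * 2^config$dereg_log2
      }
    }
    mu <- w / sum(w) * config$reads_per_replicate
    counts[, j] <- nb_draw(mu, config$nb_dispersion)
  }
  list(counts = counts, samples = samples[], truth = truth)
}

#' Emit adapter-prefixed FASTQ reads for one sample
#'
#' Each fragment with count k yields k reads: the DamID adapter followed
#' by up to `read_length` bp of genome sequence starting at the
#' fragment's GATC site, truncated at the fragment end. A configurable
#' fraction of decoy reads is interleaved: half without the adapter,
#' half adapter-prefixed but not GATC-anchored.
#'
#' @param counts integer vector of per-fragment counts
#' @param genome a [simulate_genome()] result
#' @param config a [simulation_config()] (adapter read length etc.)
#' @param decoy_fraction fraction of the emitted reads that are decoys
#' @param adapter adapter sequence (default the DamID adapter)
#' @param seed RNG seed for decoy generation and shuffling
#' @param path optional FASTQ output path
#' @return data.table(id, seq) of the emitted reads (invisibly written
#'   to `path` if given)
#' @export
emit_fastq <- function(counts, genome, config, decoy_fraction = 0,
                       adapter = "CGCGGCCGAG", seed = 1, path = NULL) {
  fr <- genome$fragments
  stopifnot(length(counts) == nrow(fr))
  idx <- rep(seq_len(nrow(fr)), counts)
  starts <- fr$start[idx]
  ends <- pmin(starts + config$read_length, fr$end[idx])
  genomic <- substr(genome$sequences[fr$chrom[idx]], starts + 1, ends)
  within_id <- sequence(counts[counts > 0])
  reads <- data.table::data.table(
    id = paste0("frag", fr$fragment_id[idx], "_", within_id),
    seq = paste0(adapter, genomic)
  )
  if (decoy_fraction > 0) {
    set.seed(seed)
    n_decoy <- round(decoy_fraction / (1 - decoy_fraction) * nrow(reads))
    rand_seq <- function(n, len) {
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "T"), len, replace = TRUE), collapse = ""),
        character(1))
    }
    n1 <- ceiling(n_decoy / 2); n2 <- n_decoy - n1
    # no-adapter decoys (A/C/T only, so the G-containing adapter and the
    # GATC motif cannot occur by chance)
    d1 <- data.table::data.table(
      id = paste0("decoy_noadapter_", seq_len(n1)),
      seq = rand_seq(n1, config$read_length + nchar(adapter)))
    d2 <- data.table::data.table(
      id = paste0("decoy_nogatc_", seq_len(n2)),
      seq = paste0(adapter, rand_seq(n2, config$read_length)))
    reads <- data.table::rbindlist(list(reads, d1, d2))
    reads <- reads[sample(.N)]
  }
  if (!is.null(path)) write_fastq(reads, path)
  invisible(reads)
}
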