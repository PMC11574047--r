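# RNA polymerase DamID (RAPID): per-gene Pol II occupancy, expressed-gene
# calling against a permutation null, and replicate-consistent
# differential expression between genotypes.

#' Per-gene RNA polymerase occupancy
#'
#' Occupancy is log2(Dam::RPB-6 / GFP::Dam) on gene-summed, pseudocounted
#' relative counts, formed per replicate pair (paired by replicate index)
#' and averaged. Unlike the binding tracks, occupancy is NOT genome-mean
#' centered: the zero point is the Dam-only accessibility baseline.
#'
#' @param rpb6_frag_reps fragments x replicates count matrix for
#'   Dam::RPB-6
#' @param gfp_frag_reps fragments x replicates count matrix for GFP::Dam
#'   (same replicate count, paired by column)
#' @param fragments fragment table
#' @param genes extended gene intervals ([gene_intervals()])
#' @param pseudocount added per gene before scaling (default 1)
#' @return list with `occupancy` (genes x replicates matrix) and
#'   `average` (named vector)
#' @export
gene_occupancy <- function(rpb6_frag_reps, gfp_frag_reps, fragments, genes,
                           pseudocount = 1) {
  r <- as_rep_matrix(rpb6_frag_reps); g <- as_rep_matrix(gfp_frag_reps)
  if (ncol(r) != ncol(g)) stop("replicate count mismatch (RPB-6 vs control)")
  if (any(colSums(r) == 0) || any(colSums(g) == 0))
    stop("empty sample: a replicate has zero total reads")
  gr <- gene_counts(r, fragments, genes)
  gg <- gene_counts(g, fragments, genes)
  rel <- function(m) { mp <- m + pseudocount; sweep(mp, 2, colSums(mp), "/") }
  occ <- log2(rel(gr) / rel(gg))
  rownames(occ) <- genes$gene_id
  list(occupancy = occ,
       average = stats::setNames(rowMeans(occ), genes$gene_id))
}

#' RAPID gene table: occupancy plus expressed-gene p/q-values
#'
#' The p-value for "expressed" comes from a one-sided test of occupancy
#' against an empirical null built by permuting the fragment-to-gene
#' assignment labels `B` times (preserving every gene's fragment count)
#' and recomputing occupancies. Permuted draws are pooled within strata
#' of genes with similar fragment counts (comparable sampling variance),
#' and the null's location and scale are estimated robustly per stratum
#' from the median and lower decile of the pooled draws; the one-sided
#' p-value is the upper normal tail at the observed occupancy. Using
#' only the lower half of the permuted distribution keeps genuinely
#' Pol II-bound fragments -- which permuted gene-shaped sets pick up by
#' chance -- from inflating the null spread, and the parametric tail
#' gives BH the resolution a raw exceedance count at B = 1000 cannot
#' (minimum p 1e-3). BH is applied over genes.
#'
#' @inheritParams gene_occupancy
#' @param B number of permutations (default 1000; below 100 the p-value
#'   tail is unstable and a warning is issued)
#' @param n_strata number of fragment-count strata for the pooled null
#'   (default 6)
#' @param seed RNG seed for the permutations
#' @param fdr FDR threshold stored with the table (default 0.05)
#' @return data.table(gene_id, occupancy per replicate, average, p_value,
#'   q_value, expressed)
#' @export
rapid_gene_table <- function(rpb6_frag_reps, gfp_frag_reps, fragments,
                             genes, pseudocount = 1, B = 1000,
                             seed = 1, fdr = 0.05, n_strata = 6) {
  if (B < 100) warning("B < 100 permutations: unstable p-value tail")
  occ <- gene_occupancy(rpb6_frag_reps, gfp_frag_reps, fragments, genes,
                        pseudocount)
  r <- as_rep_matrix(rpb6_frag_reps); g <- as_rep_matrix(gfp_frag_reps)
  R <- ncol(r)
  # fragment -> gene assignment by midpoint (0 = intergenic); permuting
  # this vector reassigns fragments while keeping per-gene fragment counts
  mid <- (fragments$start + fragments$end) %/% 2L
  fr <- data.table::data.table(chrom = fragments$chrom, start = mid,
                               end = mid + 1L,
                               frag_row = seq_len(nrow(fragments)))
  ge <- data.table::data.table(chrom = genes$chrom,
                               start = as.integer(genes$start),
                               end = as.integer(genes$end),
                               gene_row = seq_len(nrow(genes)))
  data.table::setkey(ge, chrom, start, end)
  ov <- data.table::foverlaps(fr, ge, type = "within", nomatch = NULL)
  # a fragment under overlapping extended genes keeps one label (the
  # first); the null only needs the count-per-gene structure
  assign <- rep(0L, nrow(fragments))
  ovu <- ov[!duplicated(ov$frag_row)]
  assign[ovu$frag_row] <- ovu$gene_row
  nG <- nrow(genes)
  obs <- occ$average
  # fragment-count strata: genes with similar fragment counts share a
  # pooled null (their occupancy sampling variances are comparable)
  nfrag <- tabulate(assign, nbins = nG)
  br <- unique(stats::quantile(nfrag, seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(nfrag, breaks = br, include.lowest = TRUE, labels = FALSE)
  strata <- split(seq_len(nG), stratum)
  draws <- matrix(NA_real_, nrow = nG, ncol = B)
  gene_sums <- function(lab, m) {
    out <- matrix(0, nrow = nG, ncol = ncol(m))
    keep <- lab > 0
    if (any(keep)) {
      agg <- rowsum(m[keep, , drop = FALSE], group = lab[keep])
      out[as.integer(rownames(agg)), ] <- agg
    }
    out
  }
  rel <- function(m, tot) sweep(m + pseudocount, 2, tot, "/")
  set.seed(seed)
  for (b in seq_len(B)) {
    lab <- sample(assign)
    sr <- gene_sums(lab, r); sg <- gene_sums(lab, g)
    # totals of (gene + pseudocount) per replicate for the permuted layout
    draws[, b] <- rowMeans(log2(rel(sr, colSums(sr) + nG * pseudocount) /
                                  rel(sg, colSums(sg) + nG * pseudocount)))
  }
  p <- rep(NA_real_, nG)
  for (st in strata) {
    d <- draws[st, , drop = FALSE]
    mu0 <- stats::median(d)
    sd0 <- (mu0 - stats::quantile(d, 0.1, names = FALSE)) /
      stats::qnorm(0.9)
    sd0 <- max(sd0, 1e-6)
    p[st] <- stats::pnorm(obs[st], mean = mu0, sd = sd0,
                          lower.tail = FALSE)
  }
  q <- benjamini_hochberg(p)
  out <- data.table::data.table(gene_id = genes$gene_id)
  for (k in seq_len(R)) out[[paste0("occupancy_rep", k)]] <- occ$occupancy[, k]
  out$average <- occ$average
  out$p_value <- p
  out$q_value <- q
  out$expressed <- q < fdr & occ$average > 0
  data.table::setattr(out, "B", B)
  data.table::setattr(out, "fdr", fdr)
  out
}

#' Expressed genes from a RAPID gene table
#'
#' @param table a [rapid_gene_table()] result
#' @param fdr FDR threshold (default 0.05); expressed genes additionally
#'   require positive average occupancy
#' @return character vector of gene ids
#' @export
call_expressed <- function(table, fdr = 0.05) {
  table$gene_id[table$q_value < fdr & table$average > 0]
}

#' Replicate-consistent deregulated genes between genotypes
#'
#' Per gene, the occupancy difference (mutant - wild-type) is formed for
#' each replicate pair (paired by index). A gene is called `up` when
#' every replicate delta exceeds `threshold` AND the average delta does
#' (strict inequalities); `down` symmetrically below `-threshold`. Only
#' genes in `expressed_union` (expressed in either genotype) are
#' evaluated. Swapping the genotypes swaps the up and down sets exactly.
#'
#' @param wt,mut [rapid_gene_table()] results over the same gene universe
#'   with the same replicate count
#' @param expressed_union character vector of gene ids to evaluate
#' @param threshold minimum |delta log2| (default 1, i.e. 2-fold)
#' @return data.table(gene_id, delta per replicate, average_delta,
#'   direction in {up, down, none})
#' @export
call_deregulated <- function(wt, mut, expressed_union, threshold = 1.0) {
  stopifnot(identical(wt$gene_id, mut$gene_id))
  repcols <- grep("^occupancy_rep", names(wt), value = TRUE)
  if (!identical(repcols, grep("^occupancy_rep", names(mut), value = TRUE)))
    stop("replicate count mismatch between genotypes")
  deltas <- as.matrix(mut[, repcols, with = FALSE]) -
    as.matrix(wt[, repcols, with = FALSE])
  avg <- rowMeans(deltas)
  up <- rowSums(deltas > threshold) == ncol(deltas) & avg > threshold
  down <- rowSums(deltas < -threshold) == ncol(deltas) & avg < -threshold
  direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  out <- data.table::data.table(gene_id = wt$gene_id)
  for (k in seq_len(ncol(deltas))) out[[paste0("delta_rep", k)]] <- deltas[, k]
  out$average_delta <- avg
  out$direction <- direction
  out[!(out$gene_id %in% expressed_union), direction := "none"]
  out
}

#' Join deregulated genes with their DamID binding values
#'
#' For each direction class the per-gene centered log2 binding values of
#' the wild-type and mutant fusion are paired and compared with a
#' two-sided paired t-test on the differences (mutant - wild-type),
#' optionally excluding outlier pairs whose difference lies outside
#' 1.5 x IQR of the quartiles of the differences.
#'
#' @param dereg a [call_deregulated()] result
#' @param wt_track,mut_track named per-gene centered log2 ratio tracks
#'   ([gene_level_values()]) for the wild-type and mutant fusion
#' @param exclude_outliers apply the 1.5 x IQR rule (default TRUE)
#' @return list with `table` (gene, direction, wt/mut binding, diff) and
#'   `tests` (per direction: n, mean_diff, t, p_value; NA when fewer than
#'   3 pairs survive)
#' @export
crosslink_deregulated_to_binding <- function(dereg, wt_track, mut_track,
                                             exclude_outliers = TRUE) {
  genes <- intersect(dereg$gene_id[dereg$direction != "none"],
                     intersect(names(wt_track), names(mut_track)))
  tab <- data.table::data.table(
    gene_id = genes,
    direction = dereg$direction[match(genes, dereg$gene_id)],
    wt_binding = unname(wt_track[genes]),
    mut_binding = unname(mut_track[genes])
  )
  tab[, diff := mut_binding - wt_binding]
  run_test <- function(d) {
    if (length(d) >= 3 && exclude_outliers) {
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      d <- d[d >= q[1] - 1.5 * iqr & d <= q[2] + 1.5 * iqr]
    }
    if (length(d) < 3)
      return(list(n = length(d), mean_diff = NA_real_, t = NA_real_,
                  p_value = NA_real_))
    if (stats::sd(d) == 0) {
      # degenerate spread: identical tracks give t = 0, p = 1; an exactly
      # constant nonzero shift gives an unbounded t statistic
      if (all(d == 0))
        return(list(n = length(d), mean_diff = 0, t = 0, p_value = 1))
      return(list(n = length(d), mean_diff = mean(d), t = Inf, p_value = 0))
    }
    tt <- stats::t.test(d)
    list(n = length(d), mean_diff = unname(tt$estimate),
         t = unname(tt$statistic), p_value = tt$p.value)
  }
  dirs <- c("up", "down")
  tests <- data.table::rbindlist(lapply(dirs, function(dd) {
    d <- tab$diff[tab$direction == dd]
    if (length(d) < 3)
      return(data.table::data.table(direction = dd, n = length(d),
                                    mean_diff = NA_real_, t = NA_real_,
                                    p_value = NA_real_))
    res <- run_test(d)
    data.table::data.table(direction = dd, n = res$n,
                           mean_diff = res$mean_diff, t = res$t,
                           p_value = res$p_value)
  }))
  list(table = tab, tests = tests)
}
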