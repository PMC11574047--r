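# Statistical calling: negative-binomial Wald enrichment (DESeq2-style,
# reimplemented), Benjamini-Hochberg FDR, differential association,
# arm/center distribution comparisons.

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return q-values in the input order; `q_i >= p_i`, monotone
#'   non-decreasing after sorting by p
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n * p[o] / seq(n, 1)))[ro]
  q
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across units of the
#' ratio of each count to the unit's geometric mean over all samples
#' (units with any zero are excluded from the reference). Falls back to
#' relative library size when no unit is everywhere-positive.
#'
#' @param counts units x samples count matrix
#' @return numeric vector of size factors (geometric mean 1)
#' @export
estimate_size_factors <- function(counts) {
  m <- as_rep_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (any(pos)) {
    logg <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - logg)))
  } else {
    ls <- colSums(m)
    sf <- ls / exp(mean(log(ls)))
  }
  sf / exp(mean(log(sf)))
}

# Method-of-moments per-unit NB dispersions on size-factor-normalized
# counts, shrunk in moment space toward a fitted mean-dispersion trend
# alpha(mu) = a0 + a1/mu (prior weight `prior_df` pseudo-degrees of
# freedom, residual weight n - 2).
estimate_dispersions <- function(norm, condition, sf, prior_df = 10) {
  n <- ncol(norm)
  mu <- rowMeans(norm)
  groups <- split(seq_len(n), condition)
  ssq <- rowSums(sapply(groups, function(j) {
    if (length(j) < 2) return(rep(0, nrow(norm)))
    (length(j) - 1) * apply(norm[, j, drop = FALSE], 1, stats::var)
  }))
  df <- sum(pmax(lengths(groups) - 1, 0))
  if (df == 0) {  # single replicate per side: Poisson fallback
    return(list(alpha = rep(0, nrow(norm)), poisson = TRUE))
  }
  v <- ssq / df
  xi <- mean(1 / sf)           # sampling-variance correction for scaling
  raw <- (v - xi * mu) / mu^2
  raw[!is.finite(raw)] <- NA
  use <- is.finite(raw) & raw > 0 & mu > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-6)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(raw[use], na.rm = TRUE), 1e-6); a1 <- 0
    if (!is.finite(a0)) a0 <- 1e-6
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  rawp <- pmax(raw, 0); rawp[is.na(rawp)] <- trend[is.na(rawp)]
  alpha <- (df * rawp + prior_df * trend) / (df + prior_df)
  list(alpha = pmax(alpha, 1e-8), poisson = FALSE,
       trend_coefs = c(a0 = a0, a1 = a1))
}

# Vectorized per-unit NB group-mean MLE with log link and size-factor
# offsets; returns log means and Fisher information per group.
nb_group_fit <- function(y, sf, alpha, iter = 30, tol = 1e-10) {
  tot <- as.vector(y %*% (1 / sf)) / length(sf)
  eta <- log(pmax(rowMeans(sweep(y, 2, sf, "/")), 1e-8))
  for (it in seq_len(iter)) {
    mu <- exp(eta) %o% sf                       # units x samples
    w <- 1 / (1 + alpha * mu)
    U <- rowSums((y - mu) * w)
    J <- rowSums(mu * w)
    step <- U / pmax(J, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  J <- rowSums(mu / (1 + alpha * mu))
  # all-zero groups: treat as half a count to keep the Wald stat finite
  zero <- rowSums(y) == 0
  if (any(zero)) {
    eta[zero] <- log(0.5 / sum(sf))
    mu0 <- exp(eta[zero]) %o% sf
    J[zero] <- rowSums(mu0 / (1 + alpha[zero] * mu0))
  }
  list(eta = eta, info = J)
}

#' Negative-binomial Wald enrichment test (fusion vs control)
#'
#' A self-contained stand-in for DESeq2's default analysis: median-of-
#' ratios size factors over all samples, per-unit method-of-moments NB
#' dispersions shrunk toward a global mean-dispersion trend, per-group
#' mean fit by Newton iteration with size-factor offsets, and a Wald test
#' on the log2 fold change (fusion over control). P-values are two-sided;
#' the `enriched` flag additionally requires a positive fold change
#' (`significantly more reads` in the fusion) and BH q below `fdr`.
#'
#' With a single replicate per side the dispersion cannot be estimated
#' and the test degrades to Poisson (`alpha = 0`), flagged in the
#' attributes.
#'
#' @param fusion_reps units x replicates count matrix for the fusion
#' @param control_reps units x replicates count matrix for the control
#' @param fdr FDR threshold for the `enriched` flag (default 0.05)
#' @param prior_df prior pseudo-df for dispersion shrinkage toward the
#'   trend (default 10)
#' @return data.table with per-unit `base_mean`, `log2fc`, `stat`,
#'   `pval`, `qval`, `enriched`; class `enrichment_table`
#' @export
nb_enrichment_test <- function(fusion_reps, control_reps, fdr = 0.05,
                               prior_df = 10) {
  f <- as_rep_matrix(fusion_reps); ctl <- as_rep_matrix(control_reps)
  if (nrow(f) != nrow(ctl)) stop("replicate matrices have mismatched length")
  y <- cbind(ctl, f)
  condition <- rep(c(0L, 1L), c(ncol(ctl), ncol(f)))
  sf <- estimate_size_factors(y)
  norm <- sweep(y, 2, sf, "/")
  disp <- estimate_dispersions(norm, condition, sf, prior_df)
  alpha <- disp$alpha
  fit0 <- nb_group_fit(y[, condition == 0, drop = FALSE],
                       sf[condition == 0], alpha)
  fit1 <- nb_group_fit(y[, condition == 1, drop = FALSE],
                       sf[condition == 1], alpha)
  beta <- fit1$eta - fit0$eta
  se <- sqrt(1 / fit0$info + 1 / fit1$info)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  allzero <- rowSums(y) == 0
  pval[allzero] <- 1; z[allzero] <- 0; beta[allzero] <- 0
  qval <- benjamini_hochberg(pval)
  out <- data.table::data.table(
    base_mean = rowMeans(norm),
    log2fc = beta / log(2),
    stat = z,
    pval = pval,
    qval = qval,
    enriched = qval < fdr & beta > 0
  )
  data.table::setattr(out, "class",
                      c("enrichment_table", class(out)))
  data.table::setattr(out, "size_factors", sf)
  data.table::setattr(out, "poisson_fallback", isTRUE(disp$poisson))
  data.table::setattr(out, "fdr", fdr)
  out
}

#' Differential chromatin accessibility between two tissues
#'
#' Runs the NB enrichment test in both directions on Dam-only (GFP::Dam)
#' samples binned at 2 kb, and reports the number of differential bins and
#' the percent of genome they cover in each direction.
#'
#' @param tissue1_reps,tissue2_reps bins x replicates count matrices
#' @param bin_size bin width used (default 2000)
#' @param genome_length total genome length in bp for the percent report
#' @param fdr FDR threshold (default 0.05)
#' @return list with `up_in_tissue1`, `up_in_tissue2` (enrichment
#'   tables), `n_bins` and `percent_of_genome` per direction
#' @export
differential_accessibility <- function(tissue1_reps, tissue2_reps,
                                       bin_size = 2000, genome_length,
                                       fdr = 0.05) {
  up1 <- nb_enrichment_test(tissue1_reps, tissue2_reps, fdr = fdr)
  up2 <- nb_enrichment_test(tissue2_reps, tissue1_reps, fdr = fdr)
  n1 <- sum(up1$enriched); n2 <- sum(up2$enriched)
  list(
    up_in_tissue1 = up1, up_in_tissue2 = up2,
    n_bins = c(tissue1 = n1, tissue2 = n2),
    percent_of_genome = c(
      tissue1 = percent_of_genome(n1, bin_size, genome_length),
      tissue2 = percent_of_genome(n2, bin_size, genome_length)
    )
  )
}

#' Bins preferentially associated with one of two fusion proteins
#'
#' A bin is A-preferential when it is significantly enriched for A over
#' the Dam-only control and the difference of the normalized tracks
#' (A - B) exceeds `min_delta_log2` (strictly). The two output sets are
#' disjoint by construction. When arm/center labels are supplied, each
#' set's arm bias is tested against the genome-wide arm fraction with a
#' binomial test.
#'
#' @param enrich_a,enrich_b enrichment tables vs control on the same grid
#' @param track_a,track_b centered log2 ratio tracks on the same grid
#' @param min_delta_log2 minimum |track difference| (default 0.58, i.e. a
#'   1.5-fold change)
#' @param labels optional arm/center labels per bin (from
#'   [classify_arm_center()]); `not_applicable` bins are ignored in the
#'   bias test
#' @return list with logical index vectors `a_preferential`,
#'   `b_preferential`, and (if labelled) per-set arm counts and binomial
#'   p-values
#' @export
differential_association <- function(enrich_a, enrich_b, track_a, track_b,
                                     min_delta_log2 = 0.58,
                                     labels = NULL) {
  n <- length(track_a)
  if (length(track_b) != n || nrow(enrich_a) != n || nrow(enrich_b) != n)
    stop("grid mismatch between enrichment tables and tracks")
  delta <- track_a - track_b
  a_pref <- enrich_a$enriched & delta > min_delta_log2
  b_pref <- enrich_b$enriched & (-delta) > min_delta_log2
  out <- list(a_preferential = a_pref, b_preferential = b_pref,
              n = c(a = sum(a_pref), b = sum(b_pref)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    auto <- labels != "not_applicable"
    p_arm <- mean(labels[auto] == "arm")
    arm_stats <- function(sel) {
      sel <- sel & auto
      k <- sum(labels[sel] == "arm"); m <- sum(sel)
      p <- if (m > 0) stats::binom.test(k, m, p = p_arm)$p.value else NA_real_
      list(n = m, n_arm = k,
           percent_arm = if (m > 0) 100 * k / m else NA_real_,
           p_value = p)
    }
    out$genome_arm_fraction <- p_arm
    out$a_arm <- arm_stats(a_pref)
    out$b_arm <- arm_stats(b_pref)
  }
  out
}

#' Compare a track's distribution between arm/center (or arbitrary) groups
#'
#' Per-group median and quartiles plus two-sided Wilcoxon rank-sum tests
#' for every group pair, BH-adjusted over the pair set. Exact enumeration
#' is used for small tie-free groups (both n < 50), the normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param values numeric track values (autosomal bins)
#' @param groups group label per value (e.g. arm/center, or arm classes)
#' @return list with `summary` (data.table per group) and `pairs`
#'   (data.table group1, group2, p_value, q_value); groups of fewer than
#'   2 values yield NA p-values
#' @export
arm_center_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups) & groups != "not_applicable"
  values <- values[keep]; groups <- as.character(groups[keep])
  gl <- sort(unique(groups))
  sm <- data.table::rbindlist(lapply(gl, function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.table::data.table(group = g, n = length(v),
                           q1 = q[1], median = q[2], q3 = q[3])
  }))
  if (length(gl) < 2) {
    return(list(summary = sm,
                pairs = data.table::data.table(group1 = character(0),
                                               group2 = character(0),
                                               p_value = numeric(0),
                                               q_value = numeric(0))))
  }
  cmb <- utils::combn(gl, 2)
  pv <- apply(cmb, 2, function(pr) {
    x <- values[groups == pr[1]]; y <- values[groups == pr[2]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    exact <- length(x) < 50 && length(y) < 50 &&
      !anyDuplicated(c(x, y))
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  })
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  if (any(ok)) qv[ok] <- benjamini_hochberg(pv[ok])
  list(summary = sm,
       pairs = data.table::data.table(group1 = cmb[1, ], group2 = cmb[2, ],
                                      p_value = pv, q_value = qv))
}

#' Write an enrichment table as TSV, and its significant bins as BED
#'
#' @param enrich an `enrichment_table`
#' @param grid bin grid the table was computed on
#' @param path output TSV path
#' @param bed_path optional BED of enriched bins (the "gray bar" track)
#' @export
write_enrichment_table <- function(enrich, grid, path, bed_path = NULL) {
  out <- data.table::data.table(chrom = grid$chrom, start = grid$start,
                                end = grid$end)
  out <- cbind(out, as.data.frame(enrich))
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(bed_path))
    write_bed(out[enrich$enriched == TRUE, ], bed_path)
  invisible(path)
}
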