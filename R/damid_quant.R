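# DamID quantification: adapter/GATC read filtering, fragment counting,
# binning, and the pseudocount -> relative reads -> replicate average ->
# log2 ratio -> genome-mean centering normalization chain.

#' DamID read filter parameters
#'
#' @param adapter the DamID adapter sequence retained reads must contain
#' @param require_gatc_anchor if TRUE, the post-adapter sequence must both
#'   start with GATC and match the genome at a GATC site start
#' @export
read_filter_params <- function(adapter = "CGCGGCCGAG",
                               require_gatc_anchor = TRUE) {
  stopifnot(nzchar(adapter))
  list(adapter = adapter, require_gatc_anchor = require_gatc_anchor)
}

# Exact-match lookup from a read's genomic part to the GATC fragment it
# came from. A read maps iff its post-adapter sequence equals the first
# min(read_length, fragment length) bases of a GATC-anchored fragment.
# This is the toy aligner paired with emit_fastq(); true short-read
# alignment is out of scope.
build_read_index <- function(gm, sequences, fragments, read_length = 50,
                             min_key = 20) {
  anchored <- fragments[fragments$gatc_anchored == TRUE, ]
  key_end <- pmin(anchored$start + read_length, anchored$end)
  keys <- substr(sequences[anchored$chrom], anchored$start + 1, key_end)
  # fragments shorter than min_key cannot be assigned unambiguously (and
  # are below the amplicon-size floor, so they carry no reads anyway)
  long_enough <- nchar(keys) >= min_key
  keys <- keys[long_enough]; anchored <- anchored[long_enough, ]
  dup <- duplicated(keys)
  if (any(dup)) {
    warning(sum(dup), " ambiguous fragment prefixes; first occurrence kept")
    keys <- keys[!dup]; anchored <- anchored[!dup, ]
  }
  list(keys = keys, fragment_id = anchored$fragment_id,
       read_length = read_length)
}

#' Filter DamID reads and assign them to GATC fragments
#'
#' A read is retained iff (a) it contains the DamID adapter and (b) the
#' sequence 3' of the first adapter occurrence starts at a genomic GATC
#' site (exact match against the genome). Retained reads are assigned to
#' the GATC fragment beginning at that site; discards are tallied by
#' reason (`no_adapter`, `no_gatc_anchor`, `unmapped`).
#'
#' @param reads data.table/data.frame with `id` and `seq` (see
#'   [read_fastq()])
#' @param params a [read_filter_params()] list
#' @param gm a `GenomeModel`
#' @param sequences named character vector of chromosome sequences
#' @param fragments fragment table from [gatc_fragments()]
#' @param read_length genomic read length used when the reads were
#'   generated (default 50)
#' @return list with `assignments` (data.table read_id, fragment_id),
#'   `n_retained`, and `discarded` (named counts by reason)
#' @export
filter_reads <- function(reads, params = read_filter_params(), gm,
                         sequences, fragments = gatc_fragments(gm),
                         read_length = 50) {
  if (!nrow(reads)) {
    warning("no reads supplied")
    return(list(assignments = data.table::data.table(read_id = character(0),
                                                     fragment_id = integer(0)),
                n_retained = 0L,
                discarded = c(no_adapter = 0L, no_gatc_anchor = 0L,
                              unmapped = 0L)))
  }
  seqs <- toupper(reads$seq)
  pos <- regexpr(params$adapter, seqs, fixed = TRUE)
  has_adapter <- pos > 0
  post <- substring(seqs, pos + nchar(params$adapter))
  anchored <- has_adapter & startsWith(post, "GATC")
  fragment_id <- rep(NA_integer_, length(seqs))
  if (params$require_gatc_anchor) {
    idx <- build_read_index(gm, sequences, fragments, read_length)
    fragment_id[anchored] <- idx$fragment_id[match(post[anchored], idx$keys)]
  } else {
    fragment_id[anchored] <- 0L   # anchored but unplaced
  }
  keep <- !is.na(fragment_id) & fragment_id > 0
  discarded <- c(
    no_adapter = sum(!has_adapter),
    no_gatc_anchor = sum(has_adapter & !anchored),
    unmapped = sum(anchored & !keep)
  )
  list(
    assignments = data.table::data.table(read_id = reads$id[keep],
                                         fragment_id = fragment_id[keep]),
    n_retained = sum(keep),
    discarded = discarded
  )
}

#' Count retained reads per GATC fragment
#'
#' @param assignments data.table with `fragment_id` (from [filter_reads()]
#'   or an external table)
#' @param fragments fragment table defining the count vector's universe
#' @return integer vector over fragments; `sum(counts)` equals the number
#'   of assigned reads
#' @export
count_fragments <- function(assignments, fragments) {
  ids <- assignments$fragment_id
  if (length(ids) && (any(ids < 1) || any(ids > nrow(fragments))))
    stop("assignment to unknown fragment id")
  counts <- tabulate(ids, nbins = nrow(fragments))
  as.integer(counts)
}

#' Sum fragment counts into fixed-size bins
#'
#' Each fragment contributes its whole count to the single bin containing
#' its midpoint, so totals are conserved at every resolution.
#'
#' @param counts integer vector or matrix (fragments x samples)
#' @param fragments fragment table (chrom, start, end)
#' @param grid bin grid from [bin_grid()]
#' @return vector or matrix of per-bin counts (rows follow `grid`)
#' @export
bin_counts <- function(counts, fragments, grid) {
  bin_size <- attr(grid, "bin_size")
  stopifnot(!is.null(bin_size))
  mid <- (fragments$start + fragments$end) %/% 2
  idx <- mid %/% bin_size
  # map (chrom, index) to the grid's dense bin ids
  first_bin <- grid[, .(first = min(bin_id)), by = chrom]
  offset <- stats::setNames(first_bin$first, first_bin$chrom)
  bin_of <- offset[fragments$chrom] + idx
  m <- as.matrix(counts)
  out <- matrix(0, nrow = nrow(grid), ncol = ncol(m))
  agg <- rowsum(m, group = bin_of)
  out[as.integer(rownames(agg)), ] <- agg
  colnames(out) <- colnames(m)
  if (is.null(dim(counts))) out[, 1] else out
}

#' Sum fragment counts into (extended) gene intervals
#'
#' A fragment contributes its count to every gene whose extended interval
#' contains the fragment midpoint (extended intervals may overlap).
#' Genes with no overlapping fragment keep a zero count and survive on
#' the pseudocount downstream.
#'
#' @param counts vector or matrix of fragment counts
#' @param fragments fragment table
#' @param genes extended gene intervals from [gene_intervals()]
#' @return vector or matrix of per-gene counts, rows ordered as `genes`
#' @export
gene_counts <- function(counts, fragments, genes) {
  mid <- (fragments$start + fragments$end) %/% 2L
  fr <- data.table::data.table(chrom = fragments$chrom,
                               start = mid, end = mid + 1L,
                               frag_row = seq_len(nrow(fragments)))
  ge <- data.table::data.table(chrom = genes$chrom,
                               start = as.integer(genes$start),
                               end = as.integer(genes$end),
                               gene_row = seq_len(nrow(genes)))
  data.table::setkey(ge, chrom, start, end)
  ov <- data.table::foverlaps(fr, ge, type = "within", nomatch = NULL)
  m <- as.matrix(counts)
  out <- matrix(0, nrow = nrow(genes), ncol = ncol(m))
  if (nrow(ov)) {
    agg <- rowsum(m[ov$frag_row, , drop = FALSE], group = ov$gene_row)
    out[as.integer(rownames(agg)), ] <- agg
  }
  rownames(out) <- genes$gene_id
  colnames(out) <- colnames(m)
  if (is.null(dim(counts))) out[, 1] else out
}

#' Normalization parameters for DamID ratio tracks
#' @param pseudocount added to every bin/gene before scaling (default 1)
#' @param center_genome_wide subtract the genome-wide mean log2 ratio
#' @param per_replicate_ratio if TRUE, form one log2 ratio per paired
#'   replicate and average those, instead of averaging relative reads
#'   first (sensitivity-analysis mode; the default follows the standard
#'   chain)
#' @export
normalization_params <- function(pseudocount = 1,
                                 center_genome_wide = TRUE,
                                 per_replicate_ratio = FALSE) {
  # pseudocount 0 is permitted as a limit case for scale-invariance checks
  stopifnot(pseudocount >= 0)
  list(pseudocount = pseudocount,
       center_genome_wide = center_genome_wide,
       per_replicate_ratio = per_replicate_ratio)
}

as_rep_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Normalized, replicate-averaged, centered log2 ratio track
#'
#' For each replicate a pseudocount is added to every unit (bin or gene)
#' and counts are scaled to relative reads (unit / replicate total).
#' Relative reads are averaged across replicates on each side, the
#' log2(fusion/control) ratio is formed per unit, and finally the
#' genome-wide mean log2 ratio is subtracted so the track is centered at
#' zero.
#'
#' @param fusion_reps units x replicates matrix (or list of vectors) of
#'   counts for the Dam-fusion samples
#' @param control_reps same for the Dam-only (GFP::Dam) control
#' @param params a [normalization_params()] list
#' @return numeric vector of centered log2 ratios, one per unit
#' @export
normalize_ratio <- function(fusion_reps, control_reps,
                            params = normalization_params()) {
  f <- as_rep_matrix(fusion_reps)
  c_ <- as_rep_matrix(control_reps)
  stopifnot(nrow(f) == nrow(c_))
  if (any(colSums(f) == 0) || any(colSums(c_) == 0))
    stop("empty sample: a replicate has zero total reads")
  rel <- function(m) {
    mp <- m + params$pseudocount
    sweep(mp, 2, colSums(mp), "/")
  }
  rf <- rel(f); rc <- rel(c_)
  if (params$per_replicate_ratio) {
    stopifnot(ncol(rf) == ncol(rc))
    vals <- rowMeans(log2(rf / rc))
  } else {
    vals <- log2(rowMeans(rf) / rowMeans(rc))
  }
  if (params$center_genome_wide) vals <- vals - mean(vals)
  vals
}

#' Gene-level normalized ratio track
#'
#' Applies the full normalization chain over the gene universe: fragment
#' counts are summed into 500 bp-extended gene intervals, then
#' pseudocounted, scaled, replicate-averaged, log2-ratioed and centered
#' over genes.
#'
#' @inheritParams normalize_ratio
#' @param fusion_frag_reps,control_frag_reps fragments x replicates count
#'   matrices
#' @param fragments fragment table
#' @param genes extended gene intervals ([gene_intervals()])
#' @return named numeric vector of centered per-gene log2 ratios
#' @export
gene_level_values <- function(fusion_frag_reps, control_frag_reps,
                              fragments, genes,
                              params = normalization_params()) {
  gf <- gene_counts(as_rep_matrix(fusion_frag_reps), fragments, genes)
  gc_ <- gene_counts(as_rep_matrix(control_frag_reps), fragments, genes)
  vals <- normalize_ratio(gf, gc_, params)
  stats::setNames(vals, genes$gene_id)
}
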