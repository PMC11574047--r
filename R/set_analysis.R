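# Gene-set algebra and report arithmetic: associated-gene calling,
# two-set Venn summaries, multi-dataset membership, and expression-
# category boxplot summaries.

#' Call genes associated with a fusion protein
#'
#' Genes significantly enriched for the fusion over the Dam-only control
#' in a gene-level NB enrichment test (q below `fdr`, positive fold).
#'
#' @param gene_enrichment an `enrichment_table` computed on gene-summed
#'   counts ([nb_enrichment_test()]), with gene ids in `gene_id` or as a
#'   separate `gene_ids` argument
#' @param gene_ids character vector aligned with the table rows
#' @param fdr FDR threshold (default 0.05); 0 yields the empty set
#' @return character vector of associated gene ids
#' @export
call_associated_genes <- function(gene_enrichment, gene_ids, fdr = 0.05) {
  stopifnot(length(gene_ids) == nrow(gene_enrichment))
  gene_ids[gene_enrichment$qval < fdr & gene_enrichment$log2fc > 0]
}

#' Two-set overlap (Venn) summary
#'
#' Counts of shared and set-specific genes plus integer percentages of
#' the union (rounded half up, matching how such figures are printed).
#'
#' @param set_a,set_b character vectors of gene ids (duplicates ignored)
#' @param label_a,label_b optional labels for the report
#' @return list with `n_a`, `n_b`, `shared`, `only_a`, `only_b`, `union`,
#'   and the corresponding integer percentages (`pct_specific` covers the
#'   combined set-specific genes)
#' @export
venn2 <- function(set_a, set_b, label_a = "A", label_b = "B") {
  a <- unique(set_a); b <- unique(set_b)
  shared <- length(intersect(a, b))
  only_a <- length(setdiff(a, b)); only_b <- length(setdiff(b, a))
  un <- shared + only_a + only_b
  pct <- function(k) if (un > 0) round_half_up(100 * k / un) else NA_real_
  list(labels = c(label_a, label_b),
       n_a = length(a), n_b = length(b),
       shared = shared, only_a = only_a, only_b = only_b,
       union = un,
       pct_shared = pct(shared),
       pct_only_a = pct(only_a), pct_only_b = pct(only_b),
       pct_specific = pct(only_a + only_b))
}

#' Membership histogram across k gene sets
#'
#' How many genes of the union appear in at least two sets versus exactly
#' one, and how many appear in every set, with integer percentages of
#' the union.
#'
#' @param sets list of >= 2 character vectors
#' @return list with `union`, `n_multi` (>= 2 sets), `n_unique` (exactly
#'   1), `n_all` (all k), `histogram` (genes per membership count) and
#'   percentages
#' @export
multiset_membership <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- rowSums(sapply(sets, function(s) u %in% s))
  un <- length(u)
  hist <- tabulate(member, nbins = length(sets))
  pct <- function(k) if (un > 0) round_half_up(100 * k / un) else NA_real_
  list(union = un,
       n_multi = sum(member >= 2),
       n_unique = sum(member == 1),
       n_all = sum(member == length(sets)),
       histogram = hist,
       pct_multi = pct(sum(member >= 2)),
       pct_unique = pct(sum(member == 1)),
       pct_all = pct(sum(member == length(sets))))
}

#' Binding-track summaries by expression category
#'
#' Splits the gene universe into four categories — expressed in both
#' tissues, in one only, or in neither — and summarises a per-gene
#' binding track within each, with pairwise Wilcoxon comparisons
#' (BH-adjusted) between categories.
#'
#' @param track named per-gene track ([gene_level_values()])
#' @param expressed_tissue1,expressed_tissue2 character vectors of
#'   expressed gene ids
#' @param labels category display labels (both, tissue1-only,
#'   tissue2-only, neither)
#' @return list with `categories` (named factor over the track genes),
#'   `summary` and `pairs` as in [arm_center_compare()]
#' @export
expression_category_summary <- function(track, expressed_tissue1,
                                        expressed_tissue2,
                                        labels = c("both", "tissue1_only",
                                                   "tissue2_only",
                                                   "neither")) {
  genes <- names(track)
  stopifnot(!is.null(genes))
  in1 <- genes %in% expressed_tissue1
  in2 <- genes %in% expressed_tissue2
  cat_ <- ifelse(in1 & in2, labels[1],
                 ifelse(in1, labels[2],
                        ifelse(in2, labels[3], labels[4])))
  res <- arm_center_compare(unname(track), cat_)
  list(categories = stats::setNames(cat_, genes),
       counts = table(factor(cat_, levels = labels)),
       summary = res$summary, pairs = res$pairs)
}

#' Write gene lists as plain text (one id per line)
#'
#' For handing sets to external GO / tissue-enrichment web tools; calling
#' such tools is out of scope.
#' @param sets named list of character vectors
#' @param dir output directory
#' @export
write_gene_lists <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sets))
    writeLines(sets[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(dir)
}
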