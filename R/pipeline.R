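# Orchestration: the two end-to-end analyses (DamID binding; RAPID
# expression) over a count matrix + sample sheet, with a consolidated,
# JSON-serializable report and a reproducibility manifest.

default_pipeline_params <- function(seed = 1) {
  list(
    bin_sizes = c(2000, 10000, 100000),
    diff_bin_size = 10000,
    accessibility_bin_size = 2000,
    pseudocount = 1,
    fdr = 0.05,
    min_delta_log2 = 0.58,
    dereg_threshold = 1.0,
    gene_extension = 500,
    permutations = 1000,
    seed = seed
  )
}

check_sample_sheet <- function(samples, required) {
  miss <- setdiff(required, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

select_cols <- function(counts, samples, ...) {
  sel <- rep(TRUE, nrow(samples))
  filt <- list(...)
  for (nm in names(filt)) sel <- sel & samples[[nm]] == filt[[nm]]
  if (!any(sel)) {
    desc <- paste(names(filt), unlist(filt), sep = "=", collapse = ", ")
    stop("no samples match ", desc, " in the sample sheet")
  }
  counts[, samples$sample_id[sel], drop = FALSE]
}

#' Run the DamID binding analysis end to end
#'
#' For each tissue: normalized log2 tracks for both fusion proteins at
#' every bin size and at gene level, NB enrichment vs the Dam-only
#' control, differential association between the two fusions with
#' arm/center bias statistics, arm/center Wilcoxon comparisons, gene
#' call sets and their Venn summary; plus the 2 kb differential
#' accessibility comparison between the tissues and the 4-set
#' membership summary.
#'
#' @param counts fragments x samples count matrix (columns named by
#'   sample_id)
#' @param samples sample sheet with sample_id, construct
#'   (fusion/dam_control), fusion_name, tissue, replicate
#' @param genome list with `gm`, `genes`, `fragments` (e.g. from
#'   [simulate_genome()], or built from FASTA + GFF3)
#' @param params list as from `default_pipeline_params()`
#' @param out_dir optional directory for TSV/JSON/bedgraph outputs
#' @return report list
#' @export
run_binding_analysis <- function(counts, samples, genome,
                                 params = default_pipeline_params(),
                                 out_dir = NULL) {
  check_sample_sheet(samples, c("sample_id", "construct", "fusion_name",
                                "tissue", "replicate"))
  fr <- genome$fragments
  genes_ext <- gene_intervals(genome$genes, genome$gm$chrom_lengths,
                              params$gene_extension)
  np <- normalization_params(pseudocount = params$pseudocount)
  tissues <- unique(samples$tissue)
  fusions <- setdiff(unique(samples$fusion_name), "none")
  genome_length <- sum(as.numeric(genome$gm$chrom_lengths))
  grids <- lapply(params$bin_sizes, function(b) bin_grid(genome$gm, b))
  names(grids) <- format(params$bin_sizes, scientific = FALSE, trim = TRUE)
  report <- list(manifest = c(params, list(
    tissues = tissues, fusions = fusions, genome_bp = genome_length)))
  per_tissue <- list()
  gene_sets <- list()
  for (t in tissues) {
    ctrl <- select_cols(counts, samples, construct = "dam_control",
                        tissue = t)
    res <- list()
    tracks_by_bin <- list()
    enrich_diff <- list()
    for (b in names(grids)) {
      grid <- grids[[b]]
      ctrl_b <- bin_counts(ctrl, fr, grid)
      for (fu in fusions) {
        fus <- bin_counts(select_cols(counts, samples, construct = "fusion",
                                      fusion_name = fu, tissue = t),
                          fr, grid)
        tracks_by_bin[[b]][[fu]] <- normalize_ratio(fus, ctrl_b, np)
        if (as.integer(b) == params$diff_bin_size)
          enrich_diff[[fu]] <- nb_enrichment_test(fus, ctrl_b,
                                                  fdr = params$fdr)
      }
    }
    dgrid <- grids[[as.character(params$diff_bin_size)]]
    dmid <- (dgrid$start + dgrid$end) %/% 2
    dlab <- classify_arm_center(dgrid$chrom, dmid, genome$gm$borders,
                                known_chroms = genome$gm$chrom_names)
    dtracks <- tracks_by_bin[[as.character(params$diff_bin_size)]]
    res$differential_association <- differential_association(
      enrich_diff[[fusions[1]]], enrich_diff[[fusions[2]]],
      dtracks[[fusions[1]]], dtracks[[fusions[2]]],
      min_delta_log2 = params$min_delta_log2, labels = dlab)
    res$arm_center <- lapply(dtracks, arm_center_compare, groups = dlab)
    # gene level: tracks + NB enrichment -> associated gene sets
    ctrl_g <- gene_counts(ctrl, fr, genes_ext)
    res$gene_tracks <- list()
    for (fu in fusions) {
      fus_fr <- select_cols(counts, samples, construct = "fusion",
                            fusion_name = fu, tissue = t)
      res$gene_tracks[[fu]] <- gene_level_values(fus_fr, ctrl, fr,
                                                 genes_ext, np)
      ge <- nb_enrichment_test(gene_counts(fus_fr, fr, genes_ext), ctrl_g,
                               fdr = params$fdr)
      gene_sets[[paste(fu, t, sep = "|")]] <-
        call_associated_genes(ge, genes_ext$gene_id, fdr = params$fdr)
    }
    res$venn <- venn2(gene_sets[[paste(fusions[1], t, sep = "|")]],
                      gene_sets[[paste(fusions[2], t, sep = "|")]],
                      fusions[1], fusions[2])
    res$tracks <- tracks_by_bin
    res$enrichment <- enrich_diff
    per_tissue[[t]] <- res
  }
  report$per_tissue <- per_tissue
  report$gene_sets <- gene_sets
  if (length(gene_sets) >= 2)
    report$membership <- multiset_membership(gene_sets)
  if (length(tissues) == 2) {
    grid_acc <- grids[[as.character(params$accessibility_bin_size)]]
    acc <- differential_accessibility(
      bin_counts(select_cols(counts, samples, construct = "dam_control",
                             tissue = tissues[1]), fr, grid_acc),
      bin_counts(select_cols(counts, samples, construct = "dam_control",
                             tissue = tissues[2]), fr, grid_acc),
      bin_size = params$accessibility_bin_size,
      genome_length = genome_length, fdr = params$fdr)
    report$accessibility <- acc
  }
  if (!is.null(out_dir)) write_binding_outputs(report, grids, out_dir)
  report
}

write_binding_outputs <- function(report, grids, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(report$per_tissue)) {
    res <- report$per_tissue[[t]]
    for (b in names(res$tracks)) {
      for (fu in names(res$tracks[[b]])) {
        fn <- file.path(out_dir, sprintf("track_%s_%s_%s.bedgraph",
                                         gsub("[^A-Za-z0-9]", "", fu), t, b))
        write_bedgraph(grids[[b]], res$tracks[[b]][[fu]], fn,
                       name = paste(fu, t, b))
      }
    }
    for (fu in names(res$enrichment)) {
      b <- names(grids)[vapply(grids, nrow, 0L) ==
                          nrow(res$enrichment[[fu]])][1]
      write_enrichment_table(
        res$enrichment[[fu]], grids[[b]],
        file.path(out_dir, sprintf("enrichment_%s_%s.tsv",
                                   gsub("[^A-Za-z0-9]", "", fu), t)),
        file.path(out_dir, sprintf("enriched_%s_%s.bed",
                                   gsub("[^A-Za-z0-9]", "", fu), t)))
    }
  }
  write_gene_lists(report$gene_sets, file.path(out_dir, "gene_sets"))
  summ <- list(
    manifest = report$manifest,
    venn = lapply(report$per_tissue, `[[`, "venn"),
    membership = report$membership,
    accessibility = if (!is.null(report$accessibility)) list(
      n_bins = as.list(report$accessibility$n_bins),
      percent_of_genome = as.list(report$accessibility$percent_of_genome)),
    differential_association = lapply(report$per_tissue, function(r)
      r$differential_association[c("n", "genome_arm_fraction",
                                   "a_arm", "b_arm")])
  )
  jsonlite::write_json(summ, file.path(out_dir, "binding_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Run the RAPID expression analysis end to end
#'
#' Per tissue and genotype: RAPID gene tables (occupancy + permutation
#' FDR), expressed-gene sets, replicate-consistent deregulated genes
#' between the genotypes, and (when gene-level binding tracks are
#' supplied) the crosslink of deregulated genes to wild-type vs mutant
#' fusion binding with paired t-tests, plus the expression-category
#' summaries of binding.
#'
#' @param counts fragments x samples count matrix
#' @param samples sample sheet with sample_id, construct
#'   (rpb6/dam_control), genotype (wt/mut), tissue, replicate
#' @param genome genome bundle (`gm`, `genes`, `fragments`)
#' @param params list as from `default_pipeline_params()`
#' @param binding_gene_tracks optional: per tissue, a list of per-gene
#'   centered tracks named by fusion (wild-type first), for the
#'   crosslink and category summaries
#' @param out_dir optional output directory
#' @return report list
#' @export
run_expression_analysis <- function(counts, samples, genome,
                                    params = default_pipeline_params(),
                                    binding_gene_tracks = NULL,
                                    out_dir = NULL) {
  check_sample_sheet(samples, c("sample_id", "construct", "genotype",
                                "tissue", "replicate"))
  fr <- genome$fragments
  genes_ext <- gene_intervals(genome$genes, genome$gm$chrom_lengths,
                              params$gene_extension)
  tissues <- unique(samples$tissue)
  genotypes <- unique(samples$genotype)
  if (!all(c("wt", "mut") %in% genotypes))
    stop("expression analysis needs both genotypes (wt, mut) ",
         "in the sample sheet")
  report <- list(manifest = c(params, list(tissues = tissues)))
  per_tissue <- list()
  for (t in tissues) {
    tables <- list()
    for (g in c("wt", "mut")) {
      rpb6 <- select_cols(counts, samples, construct = "rpb6",
                          genotype = g, tissue = t)
      ctrl <- select_cols(counts, samples, construct = "dam_control",
                          genotype = g, tissue = t)
      tables[[g]] <- rapid_gene_table(
        rpb6, ctrl, fr, genes_ext, pseudocount = params$pseudocount,
        B = params$permutations,
        seed = substream_seed(params$seed, 10L + match(t, tissues) * 2L +
                                match(g, c("wt", "mut"))),
        fdr = params$fdr)
    }
    expressed <- lapply(tables, call_expressed, fdr = params$fdr)
    dereg <- call_deregulated(tables$wt, tables$mut,
                              union(expressed$wt, expressed$mut),
                              threshold = params$dereg_threshold)
    res <- list(tables = tables, expressed = expressed, deregulated = dereg,
                n_up = sum(dereg$direction == "up"),
                n_down = sum(dereg$direction == "down"))
    if (!is.null(binding_gene_tracks[[t]])) {
      tr <- binding_gene_tracks[[t]]
      res$crosslink <- crosslink_deregulated_to_binding(
        dereg, tr[[1]], tr[[2]])
    }
    per_tissue[[t]] <- res
  }
  report$per_tissue <- per_tissue
  if (length(tissues) == 2 && !is.null(binding_gene_tracks)) {
    tr <- binding_gene_tracks[[tissues[1]]]
    if (!is.null(tr))
      report$category_summary <- expression_category_summary(
        tr[[1]],
        per_tissue[[tissues[1]]]$expressed$wt,
        per_tissue[[tissues[2]]]$expressed$wt)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (t in tissues) {
      res <- per_tissue[[t]]
      for (g in names(res$tables))
        data.table::fwrite(res$tables[[g]],
                           file.path(out_dir,
                                     sprintf("rapid_%s_%s.tsv", t, g)),
                           sep = "\t")
      data.table::fwrite(res$deregulated,
                         file.path(out_dir,
                                   sprintf("deregulated_%s.tsv", t)),
                         sep = "\t")
      write_gene_lists(
        list(up = res$deregulated$gene_id[res$deregulated$direction == "up"],
             down = res$deregulated$gene_id[
               res$deregulated$direction == "down"]),
        file.path(out_dir, paste0("gene_lists_", t)))
    }
    summ <- list(
      manifest = report$manifest,
      expressed_n = lapply(per_tissue, function(r) lengths(r$expressed)),
      deregulated_n = lapply(per_tissue, function(r)
        list(up = r$n_up, down = r$n_down))
    )
    jsonlite::write_json(summ, file.path(out_dir, "expression_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Minimal command-line dispatcher
#'
#' Subcommands: `simulate` (write the synthetic study to a directory),
#' `binding` and `expression` (run an analysis over a simulated study).
#' Intended for `Rscript -e 'damidkit::damid_cli()' ...`; the R API is
#' the primary interface.
#'
#' @param args character vector (defaults to `commandArgs`)
#' @return invisibly, the report of the executed subcommand
#' @export
damid_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: damid <simulate|binding|expression> --seed <int> --out <dir>",
    sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "damid_out")
  kv <- args[-1]
  for (i in seq(1, length(kv), by = 2)) {
    key <- sub("^--", "", kv[i])
    if (i + 1 > length(kv)) stop("missing value for --", key)
    opt[[key]] <- kv[i + 1]
  }
  seed <- as.integer(opt$seed)
  cfg <- simulation_config(seed = seed)
  genome <- simulate_genome(cfg)
  params <- default_pipeline_params(seed = seed)
  out <- switch(
    cmd,
    simulate = {
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_fasta(genome$sequences, file.path(opt$out, "genome.fa"))
      write_gff3_genes(genome$genes, file.path(opt$out, "genes.gff3"))
      dam <- simulate_damid_counts(cfg, genome)
      for (j in seq_len(ncol(dam$counts)))
        write_count_table(genome$fragments, dam$counts[, j],
                          file.path(opt$out,
                                    paste0(colnames(dam$counts)[j], ".tsv")))
      data.table::fwrite(dam$samples,
                         file.path(opt$out, "sample_sheet.tsv"), sep = "\t")
      message("synthetic study written to ", opt$out)
      invisible(dam)
    },
    binding = {
      dam <- simulate_damid_counts(cfg, genome)
      run_binding_analysis(dam$counts, dam$samples, genome, params, opt$out)
    },
    expression = {
      rap <- simulate_rapid_counts(cfg, genome)
      run_expression_analysis(rap$counts, rap$samples, genome, params,
                              out_dir = opt$out)
    },
    stop("unknown subcommand: ", cmd, "\n", usage)
  )
  invisible(out)
}
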