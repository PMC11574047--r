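# File format plumbing: FASTA/FASTQ via Biostrings-compatible readers,
# GFF3 gene extraction, TSV count tables, BED/bedgraph track writers.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file (wrapped lines allowed)
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (4-line records; qualities ignored)
#'
#' @param path FASTQ file
#' @return data.table(id, seq)
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) {
    warning("empty FASTQ file: ", path)
    return(data.table::data.table(id = character(0), seq = character(0)))
  }
  stopifnot(length(ln) %% 4 == 0)
  data.table::data.table(
    id = sub("^@", "", ln[seq(1, length(ln), by = 4)]),
    seq = ln[seq(2, length(ln), by = 4)]
  )
}

#' Write reads to FASTQ with constant quality
#' @param reads data.table/data.frame with `id` and `seq`
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  q <- strrep("I", nchar(reads$seq))
  writeLines(
    as.vector(rbind(paste0("@", reads$id), reads$seq, "+", q)),
    path
  )
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps `type == "gene"` rows, parses the `ID=` attribute, and converts
#' 1-based closed coordinates to 0-based half-open.
#'
#' @param path GFF3 file
#' @return data.table(gene_id, chrom, start, end, strand)
#' @export
read_gff3_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- data.table::fread(text = ln, sep = "\t", header = FALSE,
                         col.names = c("chrom", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  f <- f[type == "gene"]
  id <- sub("^.*ID=([^;]+).*$", "\\1", f$attributes)
  data.table::data.table(
    gene_id = id, chrom = f$chrom,
    start = f$start - 1L, end = f$end,   # GFF3 1-based closed -> half-open
    strand = f$strand
  )
}

#' Read a plain gene table (TSV fallback for GFF3)
#'
#' Columns: gene_id, chrom, start, end, strand; coordinates are taken as
#' 0-based half-open.
#' @param path TSV file with header
#' @export
read_gene_table <- function(path) {
  g <- data.table::fread(path)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(g)))
  g
}

#' Write gene records as GFF3
#' @param genes data.frame(gene_id, chrom, start, end, strand), half-open
#' @param path output file
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tdamidkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand %||% "+", genes$gene_id), con)
  invisible(path)
}

#' Read/write GATC fragment count tables
#'
#' TSV with columns chrom, start, end, count (0-based half-open).
#' @param path file path
#' @export
read_count_table <- function(path) {
  x <- data.table::fread(path)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(x)))
  x
}

#' @rdname read_count_table
#' @param fragments fragment table (chrom, start, end)
#' @param counts integer vector aligned with `fragments`
#' @export
write_count_table <- function(fragments, counts, path) {
  data.table::fwrite(
    data.table::data.table(chrom = fragments$chrom, start = fragments$start,
                           end = fragments$end, count = counts),
    path, sep = "\t"
  )
  invisible(path)
}

#' Write a BED file of intervals
#' @param intervals data.frame(chrom, start, end) plus optional name col
#' @param path output file
#' @export
write_bed <- function(intervals, path) {
  nm <- intervals$name %||% rep(".", nrow(intervals))
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     nm), path)
  invisible(path)
}

#' Write a bedgraph track
#' @param intervals data.frame(chrom, start, end)
#' @param values numeric vector aligned with `intervals`
#' @param path output file
#' @param name track name for the header line
#' @export
write_bedgraph <- function(intervals, values, path, name = "damidkit") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     values), con)
  invisible(path)
}
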