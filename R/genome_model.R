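#' Chromosome lengths of the C. elegans ce11 assembly
#'
#' Named vector of bp lengths (UCSC ce11 / WBcel235), including the
#' mitochondrial genome. Used for percent-of-genome arithmetic when the
#' analysis is driven from precomputed count tables rather than a FASTA.
#'
#' @export
ce11_chrom_lengths <- c(
  chrI   = 15072434,
  chrII  = 15279421,
  chrIII = 13783801,
  chrIV  = 17493829,
  chrV   = 20924180,
  chrX   = 17718942,
  chrM   = 13794
)

#' Autosome arm/center border coordinates for C. elegans
#'
#' bp positions delimiting the gene-dense chromosome center from the
#' heterochromatin-rich distal arms, per autosome. Positions below the
#' first border or at/above the second are "arm"; the center interval is
#' left-closed, right-open. chrX is deliberately absent: no usable border
#' pair is available for it, so X-linked bins are reported as
#' `not_applicable` and excluded from arm/center statistics.
#'
#' @export
celegans_arm_borders <- data.frame(
  chrom = c("chrI", "chrII", "chrIII", "chrIV", "chrV"),
  b1 = c(3745632, 4708341, 3508994, 7317812, 8125434),
  b2 = c(10809938, 11877168, 9947268, 12176625, 13849337),
  stringsAsFactors = FALSE
)

#' Find GATC motif start positions in a nucleotide sequence
#'
#' Scans case-insensitively for exact occurrences of the 4-mer GATC (the
#' Dam methylation / DpnI cut motif). `N` never matches. The motif cannot
#' overlap itself, so a non-overlapping scan is exhaustive.
#'
#' @param sequence a single character string, or a `Biostrings::DNAString`
#' @return integer vector of 0-based motif start positions (sorted)
#' @export
find_gatc_sites <- function(sequence) {
  if (inherits(sequence, "DNAString")) {
    m <- Biostrings::matchPattern("GATC", sequence, fixed = TRUE)
    return(as.integer(Biostrings::start(m)) - 1L)
  }
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 4) return(integer(0))
  hits <- gregexpr("GATC", toupper(sequence), fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}

#' Build the GATC fragment map for one chromosome
#'
#' Fragments are the half-open intervals delimited by consecutive GATC
#' site starts, plus the terminal pieces from 0 to the first site and from
#' the last site to the chromosome end. Empty intervals (a site at
#' position 0) are suppressed. Fragments tile the chromosome exactly.
#'
#' @param sites sorted 0-based GATC start positions
#' @param chrom_length chromosome length in bp
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `gatc_anchored` (TRUE when the fragment begins at a GATC site, i.e.
#'   can seed a DamID amplicon)
#' @export
build_fragments <- function(sites, chrom_length) {
  sites <- as.integer(sites)
  stopifnot(chrom_length >= 1)
  if (length(sites)) {
    if (is.unsorted(sites, strictly = TRUE))
      stop("GATC site table is corrupt: positions not strictly increasing")
    if (sites[1] < 0 || sites[length(sites)] > chrom_length - 4)
      stop("GATC site out of chromosome bounds")
  }
  bounds <- unique(c(0L, sites, as.integer(chrom_length)))
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  data.frame(
    start = start, end = end,
    gatc_anchored = start %in% sites
  )
}

#' Construct a genome model
#'
#' The coordinate scaffold shared by all downstream stages: chromosome
#' lengths, per-chromosome GATC site maps, and (optional) autosome
#' arm/center borders. All coordinates are 0-based half-open.
#'
#' @param sequences named character vector or `DNAStringSet` of chromosome
#'   sequences; GATC sites are discovered by scanning. Alternatively pass
#'   `NULL` and supply `gatc_sites` + `chrom_lengths` directly (e.g. from
#'   a cached site table).
#' @param chrom_lengths named integer vector (required when `sequences`
#'   is NULL)
#' @param gatc_sites named list of 0-based site positions (required when
#'   `sequences` is NULL)
#' @param borders data.frame(chrom, b1, b2); defaults to the C. elegans
#'   autosome borders
#' @return an object of class `GenomeModel`
#' @export
genome_model <- function(sequences = NULL, chrom_lengths = NULL,
                         gatc_sites = NULL,
                         borders = celegans_arm_borders) {
  if (!is.null(sequences)) {
    if (inherits(sequences, "DNAStringSet")) {
      chrom_lengths <- stats::setNames(Biostrings::width(sequences),
                                       names(sequences))
      gatc_sites <- lapply(seq_along(sequences), function(i)
        find_gatc_sites(sequences[[i]]))
      names(gatc_sites) <- names(sequences)
    } else {
      stopifnot(is.character(sequences), !is.null(names(sequences)))
      chrom_lengths <- stats::setNames(nchar(sequences), names(sequences))
      gatc_sites <- lapply(sequences, find_gatc_sites)
    }
  }
  stopifnot(!is.null(chrom_lengths), !is.null(gatc_sites),
            all(names(gatc_sites) == names(chrom_lengths)))
  for (ch in names(gatc_sites)) {
    s <- gatc_sites[[ch]]
    if (length(s)) {
      stopifnot(!is.unsorted(s, strictly = TRUE),
                s[1] >= 0, s[length(s)] <= chrom_lengths[[ch]] - 4)
    }
  }
  if (!is.null(borders)) {
    borders <- borders[borders$chrom %in% names(chrom_lengths), , drop = FALSE]
    stopifnot(all(borders$b1 > 0),
              all(borders$b1 < borders$b2),
              all(borders$b2 < chrom_lengths[borders$chrom]))
  }
  structure(
    list(chrom_names = names(chrom_lengths),
         chrom_lengths = chrom_lengths,
         gatc_sites = gatc_sites,
         borders = borders),
    class = "GenomeModel"
  )
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$chrom_names), "chromosomes,",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp,",
      format(sum(lengths(x$gatc_sites)), big.mark = ","), "GATC sites\n")
  invisible(x)
}

#' GATC fragment table for a whole genome
#'
#' @param gm a `GenomeModel`
#' @return data.table(chrom, start, end, gatc_anchored, fragment_id) —
#'   fragment_id is a dense 1-based index over the genome
#' @export
gatc_fragments <- function(gm) {
  stopifnot(inherits(gm, "GenomeModel"))
  out <- data.table::rbindlist(lapply(gm$chrom_names, function(ch) {
    fr <- build_fragments(gm$gatc_sites[[ch]], gm$chrom_lengths[[ch]])
    data.table::data.table(chrom = ch, fr)
  }))
  out[, fragment_id := seq_len(.N)]
  out[]
}

#' Fixed-size bin grid over a genome
#'
#' Bins are anchored at position 0 of each chromosome; the last bin of a
#' chromosome may be shorter. Bins tile each chromosome disjointly.
#'
#' @param gm a `GenomeModel`
#' @param bin_size bin width in bp (2000, 10000 and 100000 are the
#'   resolutions used in practice; any positive width is accepted)
#' @return data.table(chrom, start, end, bin_id)
#' @export
bin_grid <- function(gm, bin_size) {
  stopifnot(inherits(gm, "GenomeModel"), bin_size >= 1)
  out <- data.table::rbindlist(lapply(gm$chrom_names, function(ch) {
    L <- gm$chrom_lengths[[ch]]
    n <- ceiling(L / bin_size)
    start <- as.integer((seq_len(n) - 1) * bin_size)
    data.table::data.table(chrom = ch, start = start,
                           end = as.integer(pmin(start + bin_size, L)))
  }))
  out[, bin_id := seq_len(.N)]
  attr(out, "bin_size") <- bin_size
  out[]
}

#' Classify positions as chromosome arm or center
#'
#' Autosomal positions below the first border or at/above the second are
#' labelled `arm`; positions in `[b1, b2)` are `center`. Chromosomes with
#' no border entry (chrX, chrM) yield `not_applicable`. Bins should be
#' classified by their midpoint.
#'
#' @param chrom character vector of chromosome names
#' @param position bp positions (same length as `chrom`, or scalar)
#' @param borders data.frame(chrom, b1, b2)
#' @param known_chroms optional chromosome universe for validation;
#'   defaults to the union of border chromosomes and common C. elegans
#'   names
#' @return character vector in {"arm", "center", "not_applicable"}
#' @export
classify_arm_center <- function(chrom, position,
                                borders = celegans_arm_borders,
                                known_chroms = NULL) {
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  if (is.null(known_chroms))
    known_chroms <- union(borders$chrom, c("chrX", "chrM"))
  bad <- setdiff(unique(chrom), known_chroms)
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  idx <- match(chrom, borders$chrom)
  out <- rep("not_applicable", n)
  has <- !is.na(idx)
  b1 <- borders$b1[idx[has]]; b2 <- borders$b2[idx[has]]
  p <- position[has]
  out[has] <- ifelse(p < b1 | p >= b2, "arm", "center")
  out
}

#' Extend gene intervals on both sides
#'
#' DamID gene-level counting includes a flank distal to the transcription
#' start and termination sites (default 500 bp), clipped to chromosome
#' bounds. Strand does not affect the extension (both sides are extended).
#'
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open) and optionally strand
#' @param chrom_lengths named vector of chromosome lengths
#' @param extension bp added on each side (default 500)
#' @return data.table with `start`/`end` replaced by the extended, clipped
#'   interval
#' @export
gene_intervals <- function(genes, chrom_lengths, extension = 500) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(genes$start < genes$end), extension >= 0)
  g <- data.table::as.data.table(genes)
  L <- chrom_lengths[g$chrom]
  stopifnot(!anyNA(L))
  g[, start := as.integer(pmax(0, start - extension))]
  g[, end := as.integer(pmin(L, end + extension))]
  g[]
}
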