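#' Round half away from zero
#'
#' Integer rounding where .5 always rounds up in magnitude, matching how
#' percentages are conventionally printed in reports (base `round()` uses
#' banker's rounding).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percent of genome covered by a set of bins
#'
#' @param n_bins number of bins
#' @param bin_size bin width in bp
#' @param genome_length total genome length in bp
#' @return percentage (0-100)
#' @export
percent_of_genome <- function(n_bins, bin_size, genome_length) {
  stopifnot(n_bins >= 0, bin_size > 0, genome_length > 0)
  100 * n_bins * bin_size / genome_length
}

#' Percent change between two values
#'
#' Positive result = reduction relative to the reference value
#' (e.g. a median lifespan falling from 16 to 12 days is a 25% reduction).
#'
#' @param reference baseline value
#' @param value new value
#' @return percent reduction relative to `reference`
#' @export
percent_change <- function(reference, value) {
  stopifnot(reference != 0)
  100 * (reference - value) / reference
}

#' Convert a log2 threshold to a fold change (and back)
#'
#' @param log2_delta threshold on the log2 scale
#' @return fold change `2^log2_delta`
#' @export
log2_to_fold_change <- function(log2_delta) 2^log2_delta

#' @rdname log2_to_fold_change
#' @param fold_change fold change (> 0)
#' @export
fold_change_to_log2 <- function(fold_change) {
  stopifnot(fold_change > 0)
  log2(fold_change)
}

# Derive a reproducible sub-seed from a root seed and a stream index so
# independent simulation stages do not share an RNG stream. Kept < 2^31.
substream_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 2654435.0 + stream * 97561.0
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
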