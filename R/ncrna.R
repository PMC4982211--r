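#' Flag reads derived from non-coding RNA by best-hit e-value
#'
#' A read is flagged as non-coding-RNA-derived if and only if its best hit
#' against the ncRNA reference (minimum e-value, ties by maximum bit score
#' then subject id; see [best_hits()]) has an e-value strictly below
#' `threshold` (default `1e-5`). Reads with no hit, or whose best hit sits at
#' or above the threshold, are retained for downstream analysis.
#'
#' @param hits reads-vs-ncRNA alignment table ([read_m8()] layout).
#' @param threshold positive e-value cutoff; strict inequality.
#' @param n_total_reads optional total number of reads in the sample
#'   (including reads with no ncRNA hit). Defaults to the number of distinct
#'   read ids in `hits`, i.e. the population the filter can see.
#' @return a list with `flagged` (character vector of flagged read ids,
#'   sorted) and `report` (one-row data.frame: `n_input_reads`,
#'   `n_flagged_ncrna`, `n_retained`, `threshold`; the first three always
#'   satisfy flagged + retained = input).
#' @export
#' @examples
#' h <- rbind(
#'   data.frame(read_id = "r1", subject_id = "rRNA1", pct_identity = 99,
#'              aln_length = 90, mismatches = 1, gap_opens = 0, q_start = 1,
#'              q_end = 90, s_start = 1, s_end = 90, e_value = 1e-6,
#'              bit_score = 150),
#'   data.frame(read_id = "r2", subject_id = "rRNA1", pct_identity = 80,
#'              aln_length = 40, mismatches = 8, gap_opens = 0, q_start = 1,
#'              q_end = 40, s_start = 1, s_end = 40, e_value = 1e-4,
#'              bit_score = 40))
#' flag_ncrna_reads(h)$flagged  # r1 only: 1e-4 is not < 1e-5
flag_ncrna_reads <- function(hits, threshold = 1e-5, n_total_reads = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive e-value", call. = FALSE)
  }
  bh <- best_hits(hits)
  flagged <- sort_c(bh$read_id[bh$e_value < threshold])
  n_seen <- nrow(bh)
  n_input <- as.integer(n_total_reads %||% n_seen)
  if (n_input < n_seen) {
    stop("`n_total_reads` (", n_input, ") is smaller than the number of ",
         "distinct reads in the hit table (", n_seen, ")", call. = FALSE)
  }
  report <- data.frame(
    n_input_reads = n_input,
    n_flagged_ncrna = length(flagged),
    n_retained = n_input - length(flagged),
    threshold = threshold
  )
  list(flagged = flagged, report = report)
}

#' Draw a random subset of reference sequences
#'
#' Samples `floor(fraction * N)` records uniformly without replacement,
#' preserving the original record order in the output. Used to build reduced
#' ncRNA reference databases; the seed is mandatory so replicate subsets are
#' reproducible.
#'
#' @param sequences an `XStringSet` (e.g. `Biostrings::DNAStringSet`), a
#'   named character vector of sequences, or a path to a FASTA file (requires
#'   the Biostrings package).
#' @param fraction sampling fraction in (0, 1]; `1` returns all records.
#' @param seed integer seed controlling the draw.
#' @return an object of the same kind as the input (file paths return an
#'   `XStringSet`), containing the sampled records in original order.
#' @export
sample_reference_subset <- function(sequences, fraction, seed) {
  stopifnot_scalar_fraction(fraction, "fraction", open_lo = TRUE,
                            open_hi = FALSE)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA files requires the Biostrings package",
           call. = FALSE)
    }
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  n <- length(sequences)
  if (n == 0L) stop("no sequence records to sample from", call. = FALSE)
  k <- floor(fraction * n + 1e-9)
  if (k < 1L) stop("fraction ", fraction, " of ", n,
                   " records selects zero sequences", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, k))
  sequences[sort(idx)]
}

#' Compare ncRNA read sets flagged with a reduced vs the full reference
#'
#' Quantifies how well a reduced ncRNA reference reproduces the read set
#' flagged with the full reference. Relative accuracy is the number of reads
#' flagged by both, divided by the total flagged using the subset; relative
#' sensitivity is the same intersection divided by the total flagged using
#' the full database. Either ratio is defined as 1 when its denominator is
#' zero (an empty flag set cannot be wrong, nor miss anything).
#'
#' @param flagged_subset character vector of read ids flagged using the
#'   reduced reference.
#' @param flagged_full character vector of read ids flagged using the full
#'   reference.
#' @return one-row data.frame: `n_common`, `n_subset_total`, `n_full_total`,
#'   `relative_accuracy`, `relative_sensitivity`.
#' @export
evaluate_subset <- function(flagged_subset, flagged_full) {
  s <- unique(as.character(flagged_subset))
  f <- unique(as.character(flagged_full))
  n_common <- length(intersect(s, f))
  acc <- if (length(s) == 0L) 1 else n_common / length(s)
  sens <- if (length(f) == 0L) 1 else n_common / length(f)
  data.frame(n_common = n_common,
             n_subset_total = length(s),
             n_full_total = length(f),
             relative_accuracy = acc,
             relative_sensitivity = sens)
}
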