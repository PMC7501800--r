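# Evolutionary-rate classification of ortholog alignments by percent
# identity, query length and gap content, including the slow-set rule.

LONG_BINS <- c(">99", "98-99", "96-98", "87-96")
SHORT_BINS <- c(">95", "90-95", "80-90", "60-80")
OUT_OF_RANGE <- "out-of-range"

# floating-point-safe test for exactly 100% identity
is_full_identity <- function(pid) pid >= 100 - 1e-9

#' Is an alignment eligible for the rate analysis?
#'
#' Orthologs enter the analysis only when the query is longer than 200
#' residues and percent identity strictly exceeds 60, to limit ortholog
#' misidentification. Vectorized over the rows of a stats table.
#'
#' @param stats Data frame from [alignment_stats()] (columns `query_length`,
#'   `percent_identity`).
#' @return Logical vector.
#' @export
eligibility <- function(stats) {
  stats$query_length > 200 & stats$percent_identity > 60
}

#' Slow-set membership
#'
#' A protein belongs to the slowly evolving set iff it has length > 304
#' residues with 100% identity (and a gap-free alignment), or length > 1102
#' residues with identity strictly above 99%. Everything else eligible is
#' fast evolving.
#'
#' @inheritParams eligibility
#' @return Logical vector.
#' @export
is_slow_set <- function(stats) {
  (stats$query_length > 304 & is_full_identity(stats$percent_identity) &
     stats$n_gap_columns == 0) |
    (stats$query_length > 1102 & stats$percent_identity > 99)
}

identity_bin_one <- function(long, pid) {
  if (long) {
    if (pid > 99) ">99"
    else if (pid > 98) "98-99"
    else if (pid > 96) "96-98"
    else if (pid >= 87) "87-96"
    else OUT_OF_RANGE
  } else {
    if (pid > 95) ">95"
    else if (pid > 90) "90-95"
    else if (pid > 80) "80-90"
    else if (pid > 60) "60-80"
    else OUT_OF_RANGE
  }
}

#' Assign evolutionary-rate classes
#'
#' Bins each eligible alignment into the length stratum (long: query
#' > 1102 aa; short: 200-1102 aa), the gap stratum (no-gaps: zero gap
#' columns), and the identity bin. Long bins are (99,100], (98,99],
#' (96,98], \[87,96\]; short bins are (95,100], (90,95], (80,90], (60,80].
#' Intervals are upper-inclusive, so a boundary identity (exactly 99, 98,
#' 96, 95, 90, 80) falls in the lower bin; long-stratum identities below 87
#' are labelled `out-of-range`. Identity is used at full floating precision.
#'
#' @inheritParams eligibility
#' @return `data.frame` with columns `length_stratum` (`"long"`/`"short"`),
#'   `gap_stratum` (`"no-gaps"`/`"with-gaps"`), `identity_bin`, `slow_set`,
#'   appended to the input columns.
#' @export
classify_rate <- function(stats) {
  if (!all(eligibility(stats)))
    stop("classify_rate() requires eligible alignments; filter with eligibility() first")
  long <- stats$query_length > 1102
  out <- stats
  out$length_stratum <- ifelse(long, "long", "short")
  out$gap_stratum <- ifelse(stats$n_gap_columns == 0, "no-gaps", "with-gaps")
  out$identity_bin <- mapply(identity_bin_one, long, stats$percent_identity)
  out$slow_set <- is_slow_set(stats)
  out
}

#' Write a classification table
#'
#' One row per protein: id, length, identity, gap columns, strata, bin and
#' slow-set flag.
#'
#' @param classified Output of [classify_rate()].
#' @param path Output TSV.
#' @export
write_classification <- function(classified, path) {
  cols <- c("query_id", "query_length", "percent_identity", "n_gap_columns",
            "length_stratum", "gap_stratum", "identity_bin", "slow_set")
  write.table(classified[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
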