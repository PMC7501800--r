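# Fixed-substitution extraction from pairwise alignments and pooled
# conservative-fraction summaries per evolutionary-rate group.

#' Extract fixed substitutions from a pairwise alignment
#'
#' Returns exactly the columns where both rows carry standard amino acids
#' that differ. Gap columns are never substitutions; columns containing an
#' ambiguity code (B, Z, X, U, O, `*`) on either row are dropped, with the
#' dropped count attached as attribute `n_ambiguous_dropped`.
#'
#' @param aln A `pairwise_aln`.
#' @return `data.frame` with columns `column` (0-based alignment column),
#'   `query_aa`, `hit_aa`; zero rows if the pair is identical.
#' @export
extract_substitutions <- function(aln) {
  stopifnot(inherits(aln, "pairwise_aln"))
  q <- strsplit(aln$qseq, "")[[1]]
  s <- strsplit(aln$sseq, "")[[1]]
  std <- q %in% AA20 & s %in% AA20
  amb <- (q %in% AA_AMBIGUOUS | s %in% AA_AMBIGUOUS) & q != "-" & s != "-"
  keep <- std & q != s
  out <- data.frame(column = which(keep) - 1L,
                    query_aa = q[keep], hit_aa = s[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_ambiguous_dropped") <- sum(amb)
  out
}

new_fraction_result <- function(n_conservative, n_total,
                                n_proteins = NA_integer_,
                                mean_length = NA_real_) {
  structure(list(n_conservative = as.integer(n_conservative),
                 n_total = as.integer(n_total),
                 fraction = if (n_total > 0) n_conservative / n_total else NA_real_,
                 defined = n_total > 0,
                 n_proteins = n_proteins, mean_length = mean_length),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("Conservative fraction: %d / %d = %.3f\n",
                x$n_conservative, x$n_total, x$fraction))
  else cat("Conservative fraction: undefined (no substitutions)\n")
  invisible(x)
}

#' Conservative fraction of a substitution set
#'
#' Counts substitutions scoring strictly above the matrix cutoff and returns
#' counts plus their ratio. A zero-substitution input yields an undefined
#' result (flagged, never 0/0).
#'
#' @param subs Data frame from [extract_substitutions()] (columns
#'   `query_aa`, `hit_aa`), or a missense variant table (columns `ref_aa`,
#'   `alt_aa`).
#' @param m An `aa_subst_matrix`.
#' @return A `fraction_result` with `n_conservative`, `n_total`, `fraction`,
#'   `defined`.
#' @export
conservative_fraction <- function(subs, m) {
  ab <- substitution_pairs(subs)
  if (nrow(ab) == 0L) return(new_fraction_result(0L, 0L))
  new_fraction_result(sum(is_conservative(m, ab[[1]], ab[[2]])), nrow(ab))
}

# accept either fixed-substitution or variant column naming
substitution_pairs <- function(subs) {
  if (all(c("query_aa", "hit_aa") %in% names(subs)))
    subs[, c("query_aa", "hit_aa")]
  else if (all(c("ref_aa", "alt_aa") %in% names(subs)))
    subs[, c("ref_aa", "alt_aa")]
  else stop("expected columns query_aa/hit_aa or ref_aa/alt_aa")
}

#' Histogram of substitution scores
#'
#' Tabulates matrix scores over a substitution set; the per-score fractions
#' sum to 1 over non-empty input.
#'
#' @inheritParams conservative_fraction
#' @return `data.frame` with columns `score`, `count`, `fraction`; zero rows
#'   for empty input.
#' @export
score_histogram <- function(subs, m) {
  ab <- substitution_pairs(subs)
  if (nrow(ab) == 0L)
    return(data.frame(score = integer(), count = integer(), fraction = numeric()))
  sc <- score_substitution(m, ab[[1]], ab[[2]])
  tab <- table(factor(sc, levels = sort(unique(sc))))
  data.frame(score = as.integer(names(tab)), count = as.integer(tab),
             fraction = as.integer(tab) / sum(tab))
}

#' Group-wise conservative fraction table (rate bins x matrices)
#'
#' Builds the rate-bin summary: for every populated (length stratum, gap
#' stratum, identity bin) cell, substitutions are pooled across the cell's
#' proteins and one conservative fraction is computed per scoring matrix,
#' alongside the number of proteins and their mean query length. Pooling
#' counts before taking the ratio (rather than averaging per-protein
#' fractions) is the default because downstream chi-squared tests operate on
#' the pooled counts; set `per_protein = TRUE` for the unweighted mean of
#' per-protein fractions instead.
#'
#' @param classified Data frame from [classify_rate()] (one row per protein).
#' @param subs_list List of substitution data frames parallel to the rows of
#'   `classified`.
#' @param matrices Named list of `aa_subst_matrix` (default all four).
#' @param per_protein Average per-protein fractions instead of pooling counts.
#' @return `data.frame` with one row per populated cell, in the canonical
#'   order (long before short, no-gaps before with-gaps, high- to
#'   low-identity bins): strata and bin columns, one fraction column per
#'   matrix plus `<name>_n_conservative`/`<name>_n_total` count columns,
#'   `n_proteins`, `mean_length`.
#' @export
group_fraction_table <- function(classified, subs_list,
                                 matrices = conservation_matrices(),
                                 per_protein = FALSE) {
  stopifnot(nrow(classified) == length(subs_list))
  bins_of <- function(stratum) if (stratum == "long") LONG_BINS else SHORT_BINS
  rows <- list()
  for (ls in c("long", "short")) for (gs in c("no-gaps", "with-gaps"))
    for (bin in c(bins_of(ls), OUT_OF_RANGE)) {
      idx <- which(classified$length_stratum == ls &
                     classified$gap_stratum == gs &
                     classified$identity_bin == bin)
      if (!length(idx)) next
      row <- data.frame(length_stratum = ls, gap_stratum = gs,
                        identity_bin = bin, stringsAsFactors = FALSE)
      pooled <- do.call(rbind, subs_list[idx])
      for (mn in names(matrices)) {
        m <- matrices[[mn]]
        if (per_protein) {
          fr <- vapply(subs_list[idx], function(s) conservative_fraction(s, m)$fraction, 0)
          row[[mn]] <- mean(fr, na.rm = TRUE)
          cf <- conservative_fraction(pooled, m)
        } else {
          cf <- conservative_fraction(pooled, m)
          row[[mn]] <- cf$fraction
        }
        row[[paste0(mn, "_n_conservative")]] <- cf$n_conservative
        row[[paste0(mn, "_n_total")]] <- cf$n_total
      }
      row$n_proteins <- length(idx)
      row$mean_length <- mean(classified$query_length[idx])
      rows[[length(rows) + 1L]] <- row
    }
  do.call(rbind, rows)
}

#' Write the rate-bin fraction table as TSV
#'
#' @param tab Output of [group_fraction_table()].
#' @param path Output TSV.
#' @export
write_fraction_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
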