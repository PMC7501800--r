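# Overlap-ratio diagnostic of mutation saturation on alignments of three or
# more taxa. A focal-pair mismatch where an outgroup differs from BOTH focal
# residues evidences repeated mutation at the site: a single substitution on
# the path separating the focal pair cannot make the outgroup differ from
# both of them.

coerce_msa_rows <- function(msa) {
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  if (is.character(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      stop("aligned rows must all have the same span")
    return(do.call(rbind, strsplit(msa, "")))
  }
  if (is.matrix(msa) && is.character(msa)) return(msa)
  stop("msa must be an AAStringSet, character vector of aligned rows, or character matrix")
}

#' Overlap ratio of a multiple alignment
#'
#' Given an alignment of at least three taxa, a column is *mismatched* when
#' the two focal residues differ, and a mismatched column is an *overlap
#' site* when at least one outgroup residue differs from both focal
#' residues, implying at least two independent substitutions at that site.
#' Columns containing a gap or ambiguity code in the focal pair or any
#' outgroup row are excluded before counting. The overlap ratio --
#' overlap sites / mismatched sites -- is the saturation diagnostic: it
#' rises 2-3-fold as repeated mutation accumulates.
#'
#' @param msa Aligned sequences: an [Biostrings::AAStringSet], a character
#'   vector of equal-length gapped strings, or a character matrix (rows =
#'   taxa). At least 3 rows.
#' @param focal Indices or names of the two focal taxa (default first two);
#'   all remaining rows are outgroups.
#' @return An `overlap_report`: `n_mismatch`, `n_overlap`, `ratio` (NA when
#'   there are no mismatched sites), `n_excluded_columns`.
#' @export
overlap_ratio <- function(msa, focal = c(1L, 2L)) {
  rows <- coerce_msa_rows(msa)
  if (!is.null(names(msa)) && is.character(focal))
    focal <- match(focal, names(msa))
  if (length(focal) != 2L || anyNA(focal)) stop("focal must name exactly two taxa")
  if (nrow(rows) < 3L) stop("need at least three taxa (two focal + >= 1 outgroup)")
  out_idx <- setdiff(seq_len(nrow(rows)), focal)
  valid <- matrix(rows %in% AA20, nrow(rows), ncol(rows))
  usable <- colSums(valid[c(focal, out_idx), , drop = FALSE]) == nrow(rows)
  a <- rows[focal[1L], ]; b <- rows[focal[2L], ]
  mism <- usable & a != b
  og <- rows[out_idx, , drop = FALSE]
  differs_both <- colSums(og != matrix(a, nrow(og), ncol(og), byrow = TRUE) &
                            og != matrix(b, nrow(og), ncol(og), byrow = TRUE)) > 0
  n_mismatch <- sum(mism)
  n_overlap <- sum(mism & differs_both)
  structure(list(n_mismatch = n_mismatch, n_overlap = n_overlap,
                 ratio = if (n_mismatch > 0) n_overlap / n_mismatch else NA_real_,
                 n_excluded_columns = sum(!usable)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap sites: %d of %d mismatched sites (ratio %s; %d column(s) excluded)\n",
              x$n_overlap, x$n_mismatch,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              x$n_excluded_columns))
  invisible(x)
}

#' Call saturation from an overlap ratio against a baseline
#'
#' Labels the alignment `"saturated-like"` when its overlap ratio is at
#' least twice the pre-saturation baseline ratio, reflecting the 2-3-fold
#' elevation expected at mutation saturation (empirically around 50-60%
#' overlap among mismatched sites, reported as context, not enforced as a
#' threshold).
#'
#' @param report,baseline `overlap_report` objects with defined ratios.
#' @return `"saturated-like"` or `"not-saturated-like"`.
#' @export
saturation_call <- function(report, baseline) {
  stopifnot(inherits(report, "overlap_report"), inherits(baseline, "overlap_report"))
  if (is.na(report$ratio) || is.na(baseline$ratio))
    stop("overlap ratio undefined (no mismatched sites)")
  if (report$ratio >= 2 * baseline$ratio) "saturated-like" else "not-saturated-like"
}

#' Write an overlap report as TSV
#'
#' @param report An `overlap_report`.
#' @param path Output TSV.
#' @export
write_overlap_report <- function(report, path) {
  df <- data.frame(n_mismatch = report$n_mismatch, n_overlap = report$n_overlap,
                   ratio = report$ratio,
                   n_excluded_columns = report$n_excluded_columns)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
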