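# Sequence and alignment I/O plus the pairwise ortholog aligner.
# Global affine-gap alignment is delegated to Biostrings::pairwiseAlignment;
# BLAST tabular-style alignment tables are supported as an alternative input
# so that real BLASTP output can be fed in instead of the internal aligner.

#' Read protein sequences from FASTA
#'
#' Order-preserving; record ids are taken up to the first whitespace, with
#' the remainder kept as the description. Residues outside the 20 standard
#' codes plus the tolerated ambiguity set (B, Z, X, U, O, `*`) are an error;
#' records containing ambiguity codes are parsed but flagged.
#'
#' @param path FASTA file.
#' @return A [Biostrings::AAStringSet] named by id, with `description` and
#'   `has_ambiguity` columns in its `mcols()`.
#' @export
read_fasta <- function(path) {
  # readAAStringSet drops characters outside its alphabet with a warning;
  # treat that as the illegal-character error it really is
  x <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("illegal residue character(s) in ", path)
      invokeRestart("muffleWarning")
    })
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L)) stop("empty sequence record in ", path)
  lets <- Biostrings::uniqueLetters(x)
  bad <- setdiff(lets, c(AA20, AA_AMBIGUOUS))
  if (length(bad))
    stop("illegal residue character(s) in ", path, ": ", paste(bad, collapse = ", "))
  amb_counts <- Biostrings::letterFrequency(x, paste(AA_AMBIGUOUS, collapse = ""))
  has_amb <- rowSums(amb_counts) > 0
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc,
                                              has_ambiguity = has_amb)
  if (any(has_amb))
    message(sum(has_amb), " record(s) contain ambiguity codes; ",
            "affected columns are excluded from scoring")
  x
}

#' Write protein sequences to FASTA
#'
#' @param seqs An [Biostrings::AAStringSet] or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

as_residue_string <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)
}

new_pairwise_aln <- function(query_id, hit_id, qseq, sseq, score) {
  if (nchar(qseq) != nchar(sseq))
    stop("aligned query and hit strings differ in length")
  structure(list(query_id = query_id, hit_id = hit_id,
                 qseq = qseq, sseq = sseq, score = score),
            class = "pairwise_aln")
}

#' @export
print.pairwise_aln <- function(x, ...) {
  cat(sprintf("Pairwise alignment %s vs %s: span %d, score %.1f\n",
              x$query_id, x$hit_id, nchar(x$qseq), x$score))
  invisible(x)
}

# extend a scoring matrix so ambiguity letters are legal during alignment
# (always at the minimum score; such columns are excluded from analysis later)
extend_scoring <- function(scores, letters_present) {
  extra <- setdiff(letters_present, rownames(scores))
  if (!length(extra)) return(scores)
  lo <- min(scores)
  n <- nrow(scores)
  out <- matrix(lo, n + length(extra), n + length(extra),
                dimnames = list(c(rownames(scores), extra),
                                c(colnames(scores), extra)))
  out[seq_len(n), seq_len(n)] <- scores
  out
}

#' Global pairwise protein alignment (affine gaps)
#'
#' Needleman-Wunsch global alignment with affine gap penalties, serving as
#' the internal surrogate for a BLASTP best-hit alignment when orthologs are
#' near full length. A gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b Sequences: character strings, or `AAString`/single-record
#'   `AAStringSet` objects. Names (or `query_id`/`hit_id`) label the result.
#' @param scoring An `aa_subst_matrix` used for match/mismatch scores
#'   (default canonical BLOSUM62).
#' @param gap_open,gap_extend Non-negative affine gap penalties
#'   (defaults 11 and 1, the BLASTP defaults).
#' @param query_id,hit_id Optional id labels.
#' @return A `pairwise_aln`: query/hit ids, aligned strings with `-` gaps,
#'   and the optimal score.
#' @export
global_align <- function(a, b, scoring = blosum62_matrix(),
                         gap_open = 11, gap_extend = 1,
                         query_id = NULL, hit_id = NULL) {
  query_id <- query_id %||% (if (!is.null(names(a))) names(a)[1] else "query")
  hit_id <- hit_id %||% (if (!is.null(names(b))) names(b)[1] else "hit")
  a <- as_residue_string(a); b <- as_residue_string(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  lets <- unique(strsplit(paste0(a, b), "")[[1]])
  sm <- extend_scoring(scoring$scores, lets)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  new_pairwise_aln(query_id, hit_id,
                   as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa)),
                   Biostrings::score(pa))
}

#' BLAST-style statistics for a pairwise alignment
#'
#' Computes query length (ungapped), alignment span (columns), the number of
#' matching residues, mismatches, combined gap columns over both rows, and
#' percent identity = 100 * matches / span -- the denominator includes gap
#' columns (BLAST convention).
#'
#' @param aln A `pairwise_aln`.
#' @return One-row `data.frame` with columns `query_id`, `hit_id`,
#'   `query_length`, `span`, `n_match`, `n_mismatch`, `n_gap_columns`,
#'   `percent_identity`.
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "pairwise_aln"))
  q <- strsplit(aln$qseq, "")[[1]]
  s <- strsplit(aln$sseq, "")[[1]]
  span <- length(q)
  if (span == 0L) stop("zero-span alignment")
  if (any(q == "-" & s == "-")) stop("gap-vs-gap column in alignment")
  gap <- q == "-" | s == "-"
  match <- !gap & q == s
  data.frame(query_id = aln$query_id, hit_id = aln$hit_id,
             query_length = sum(q != "-"), span = span,
             n_match = sum(match), n_mismatch = sum(!gap & !match),
             n_gap_columns = sum(gap),
             percent_identity = 100 * sum(match) / span,
             stringsAsFactors = FALSE)
}

#' Read a tabular alignment file (BLAST outfmt-style)
#'
#' Expects tab-separated columns `qseqid, sseqid, pident, length, gaps,
#' qlen, qseq, sseq`, where `qseq`/`sseq` carry the aligned strings with `-`
#' gaps (as produced by BLAST+ `-outfmt "6 ... qseq sseq"`). Alignments are
#' reconstructed from the aligned strings; identity is recomputed, and if it
#' disagrees with the file's `pident` by more than 0.05 a warning is issued
#' and the recomputed value is kept.
#'
#' @param path TSV file.
#' @return List with `alignments` (list of `pairwise_aln`) and `stats`
#'   (data.frame, one row per alignment).
#' @export
read_alignment_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "pident", "length", "gaps", "qlen", "qseq", "sseq")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("alignment table lacks column(s): ", paste(miss, collapse = ", "))
  alns <- vector("list", nrow(tab))
  stats <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (nchar(tab$qseq[i]) != nchar(tab$sseq[i]))
      stop("row ", i, ": aligned qseq and sseq have unequal length")
    alns[[i]] <- new_pairwise_aln(tab$qseqid[i], tab$sseqid[i],
                                  tab$qseq[i], tab$sseq[i], score = NA_real_)
    st <- alignment_stats(alns[[i]])
    if (is.finite(tab$pident[i]) &&
        abs(st$percent_identity - tab$pident[i]) > 0.05)
      warning(sprintf("row %d (%s vs %s): stated pident %.2f differs from recomputed %.2f; keeping recomputed",
                      i, tab$qseqid[i], tab$sseqid[i], tab$pident[i], st$percent_identity))
    stats[[i]] <- st
  }
  list(alignments = alns, stats = do.call(rbind, stats))
}

#' Write alignments to a tabular alignment file
#'
#' Inverse of [read_alignment_table()]; round-trips the aligned strings.
#'
#' @param alns List of `pairwise_aln`.
#' @param path Output TSV.
#' @export
write_alignment_table <- function(alns, path) {
  rows <- lapply(alns, function(a) {
    st <- alignment_stats(a)
    data.frame(qseqid = a$query_id, sseqid = a$hit_id,
               pident = st$percent_identity, length = st$span,
               gaps = st$n_gap_columns, qlen = st$query_length,
               qseq = a$qseq, sseq = a$sseq, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Choose the best hit among candidate alignments
#'
#' Selects the candidate with the maximal alignment score (the stand-in for
#' BLAST E-value ranking); ties are broken by higher percent identity, then
#' by lexicographically smallest hit id.
#'
#' @param candidates Non-empty list of `pairwise_aln` for one query.
#' @return The selected `pairwise_aln`.
#' @export
pick_best_hit <- function(candidates) {
  if (!length(candidates)) stop("no candidate alignments")
  scores <- vapply(candidates, function(a) a$score, 0)
  ident <- vapply(candidates, function(a) alignment_stats(a)$percent_identity, 0)
  ids <- vapply(candidates, function(a) a$hit_id, "")
  ord <- order(-scores, -ident, ids)
  candidates[[ord[1L]]]
}

#' Keep one isoform per gene (the longest)
#'
#' Where several protein records share a gene, retains the longest; ties are
#' broken by lexicographically smallest protein id.
#'
#' @param seqs An [Biostrings::AAStringSet].
#' @param gene Character vector of gene labels parallel to `seqs` (defaults
#'   to the record ids, i.e. no grouping).
#' @return The filtered `AAStringSet`.
#' @export
keep_longest_isoform <- function(seqs, gene = names(seqs)) {
  stopifnot(length(gene) == length(seqs))
  ord <- order(gene, -Biostrings::width(seqs), names(seqs))
  keep <- ord[!duplicated(gene[ord])]
  seqs[sort(keep)]
}
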