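# Conservativeness scoring matrices: normalized [0,1] matrices, the
# x -> round(10x - 5) integer rescaling, and the strict conservative-change
# predicate score > cutoff.

new_norm_matrix <- function(name, values) {
  ab <- rownames(values)
  structure(list(name = name, alphabet = ab, values = values),
            class = "aa_norm_matrix")
}

new_subst_matrix <- function(name, scores, cutoff) {
  storage.mode(scores) <- "integer"
  structure(list(name = name, alphabet = rownames(scores),
                 scores = scores, conservative_cutoff = as.integer(cutoff)),
            class = "aa_subst_matrix")
}

#' @export
print.aa_norm_matrix <- function(x, ...) {
  cat(sprintf("Normalized conservativeness matrix '%s' (%d residues), range [%.3g, %.3g]\n",
              x$name, length(x$alphabet), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.aa_subst_matrix <- function(x, ...) {
  cat(sprintf("Integer substitution matrix '%s' (%d residues), conservative cutoff: score > %d\n",
              x$name, length(x$alphabet), x$conservative_cutoff))
  invisible(x)
}

check_matrix_body <- function(values, path) {
  if (!all(vapply(seq_len(ncol(values)), function(j) is.numeric(values[, j]), TRUE)))
    stop("non-numeric cell in matrix file: ", path)
  m <- as.matrix(values)
  miss <- setdiff(AA20, rownames(m))
  if (length(miss))
    stop("matrix file ", path, " is missing amino acid(s): ", paste(miss, collapse = ", "))
  if (!identical(sort(rownames(m)), sort(colnames(m))))
    stop("matrix file ", path, ": row and column residue sets differ")
  m <- m[AA20, AA20]
  if (max(abs(m - t(m))) > 1e-9)
    stop("matrix file ", path, " is asymmetric beyond 1e-9; refusing to symmetrize")
  m
}

#' Load a 20x20 conservation matrix from TSV
#'
#' Reads a tab-separated matrix whose first row and first column carry the 20
#' standard one-letter amino-acid codes (any order; reordered internally to
#' the fixed `ARNDCQEGHILKMFPSTWYV` order). Lines starting with `#` are
#' comments. Validation is strict: a missing residue, a non-numeric cell,
#' asymmetry beyond 1e-9, or (for `kind = "normalized"`) an entry outside
#' \[0, 1\] is an error -- matrices are rejected, never silently repaired.
#'
#' @param path Path to the TSV file.
#' @param kind `"normalized"` for a real-valued conservativeness matrix in
#'   \[0, 1\] (higher = more conservative), `"integer"` for an integer score
#'   matrix such as BLOSUM62.
#' @param name Label for the matrix; defaults to the file name.
#' @param cutoff For `kind = "integer"`, the strict conservative-change
#'   cutoff to attach (a change is conservative iff score > cutoff).
#' @return An object of class `aa_norm_matrix` or `aa_subst_matrix`.
#' @examples
#' ex <- load_matrix(system.file("extdata", "ex_synthetic_normalized.tsv",
#'                               package = "aacons"), "normalized", name = "EX")
#' range(ex$values)
#' @export
load_matrix <- function(path, kind = c("normalized", "integer"),
                        name = NULL, cutoff = 0L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    row.names = 1, stringsAsFactors = FALSE)
  m <- check_matrix_body(tab, path)
  name <- name %||% sub("\\.tsv$", "", basename(path))
  if (kind == "normalized") {
    if (min(m) < 0 || max(m) > 1)
      stop("matrix file ", path, ": normalized entries must lie in [0, 1], found range [",
           min(m), ", ", max(m), "]")
    new_norm_matrix(name, m)
  } else {
    if (max(abs(m - round(m))) > 1e-9)
      stop("matrix file ", path, ": integer matrix has non-integer entries")
    new_subst_matrix(name, round(m), cutoff)
  }
}

#' Build a conservativeness matrix from a single property scale
#'
#' For a per-residue property p (e.g. side-chain volume), the pairwise change
#' is Delta(a,b) = |p(a) - p(b)| / max over pairs |p(x) - p(y)|, and the
#' conservativeness is its complement c(a,b) = 1 - Delta(a,b), so that
#' identical-property pairs score 1 and the most dissimilar pair scores 0.
#'
#' @param scale Named numeric vector of property values (names are one-letter
#'   residue codes; at least two residues; usually all 20).
#' @param name Label for the resulting matrix.
#' @return An `aa_norm_matrix` over the residues named in `scale`.
#' @examples
#' toy <- delta_from_scale(c(A = 0, G = 1, W = 3), "toy")
#' toy$values["A", "G"]  # 1 - (1/3)
#' @export
delta_from_scale <- function(scale, name = "delta") {
  if (length(scale) < 2L || is.null(names(scale)))
    stop("scale must be a named numeric vector with >= 2 residues")
  if (!all(is.finite(scale))) stop("scale values must be finite")
  d <- abs(outer(scale, scale, "-"))
  if (max(d) == 0) stop("all property values are equal; pairwise change is undefined")
  v <- 1 - d / max(d)
  dimnames(v) <- list(names(scale), names(scale))
  new_norm_matrix(name, v)
}

#' Rescale a normalized matrix to integer scores
#'
#' Applies s(a,b) = round(10 * v(a,b) - 5) entrywise, mapping \[0, 1\] onto
#' integer scores in \[-5, +5\]. Rounding ties (x.5) go away from zero.
#' The conservative cutoff is attached unchanged.
#'
#' @param m An `aa_norm_matrix`.
#' @param cutoff Strict conservative-change cutoff for the resulting matrix.
#' @return An `aa_subst_matrix`.
#' @export
rescale_to_integer <- function(m, cutoff) {
  if (!inherits(m, "aa_norm_matrix"))
    stop("rescale_to_integer() expects a normalized matrix (aa_norm_matrix)")
  s <- round_half_away(10 * m$values - 5)
  new_subst_matrix(m$name, s, cutoff)
}

check_residues <- function(a, b, alphabet) {
  bad <- setdiff(unique(c(a, b)), alphabet)
  if (length(bad))
    stop("nonstandard or out-of-alphabet residue(s): ", paste(bad, collapse = ", "))
  if (any(a == b))
    stop("identical residues are not a substitution (a == b)")
}

#' Score an amino-acid substitution
#'
#' Looks up the integer score of replacing residue `a` with residue `b`
#' (symmetric in its arguments). Vectorized over pairs.
#'
#' @param m An `aa_subst_matrix`.
#' @param a,b Character vectors of one-letter residue codes; `a[i] != b[i]`
#'   and both standard (ambiguity codes such as X, B, Z, U, O, `*` are
#'   rejected).
#' @return Integer vector of scores.
#' @examples
#' score_substitution(blosum62_matrix(), "F", "Y")  # 3
#' @export
score_substitution <- function(m, a, b) {
  if (!inherits(m, "aa_subst_matrix")) stop("m must be an aa_subst_matrix")
  check_residues(a, b, m$alphabet)
  m$scores[cbind(a, b)]
}

#' Is a substitution conservative?
#'
#' A change is conservative iff its matrix score strictly exceeds the
#' matrix's cutoff (score > cutoff; equality is non-conservative).
#'
#' @inheritParams score_substitution
#' @return Logical vector.
#' @export
is_conservative <- function(m, a, b) {
  score_substitution(m, a, b) > m$conservative_cutoff
}

extdata <- function(f) system.file("extdata", f, package = "aacons", mustWork = TRUE)

#' The canonical BLOSUM62 matrix
#'
#' Bundled NCBI BLOSUM62 half-bit scores over the 20 standard residues, used
#' raw (not rescaled), with conservative cutoff score > 0.
#'
#' @return An `aa_subst_matrix`.
#' @export
blosum62_matrix <- function() {
  load_matrix(extdata("blosum62.tsv"), "integer", name = "BLOSUM62", cutoff = 0L)
}

#' Exchangeability-style conservativeness matrix (synthetic stand-in)
#'
#' An integer-rescaled exchangeability-like matrix with conservative cutoff
#' score > 2. The bundled normalized matrix is a deterministic synthetic
#' construction from side-chain volume, polarity and hydropathy scales
#' (see `ex_synthetic_normalized.tsv`); it is a structural stand-in for an
#' experimentally derived exchangeability matrix, not a transcription of
#' one, and analyses using it probe the method, not published EX values.
#'
#' @return An `aa_subst_matrix` named "EX".
#' @export
ex_matrix <- function() {
  n <- load_matrix(extdata("ex_synthetic_normalized.tsv"), "normalized", name = "EX")
  rescale_to_integer(n, 2L)
}

read_property_scales <- function() {
  ps <- read.delim(extdata("property_scales.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  list(volume = setNames(ps$volume, ps$aa)[AA20],
       polarity = setNames(ps$polarity, ps$aa)[AA20])
}

#' Side-chain volume conservativeness matrix (delta_V)
#'
#' Complemented, normalized pairwise change in side-chain volume
#' (Grantham 1974 scale), integer-rescaled; conservative cutoff score > 3.
#'
#' @return An `aa_subst_matrix` named "delta_V".
#' @export
delta_v_matrix <- function() {
  sc <- read_property_scales()
  rescale_to_integer(delta_from_scale(sc$volume, "delta_V"), 3L)
}

#' Side-chain polarity conservativeness matrix (delta_P)
#'
#' Complemented, normalized pairwise change in side-chain polarity
#' (Grantham 1974 scale), integer-rescaled; conservative cutoff score > 3.
#'
#' @return An `aa_subst_matrix` named "delta_P".
#' @export
delta_p_matrix <- function() {
  sc <- read_property_scales()
  rescale_to_integer(delta_from_scale(sc$polarity, "delta_P"), 3L)
}

#' The four conservativeness matrices used throughout the analysis
#'
#' @return Named list of `aa_subst_matrix`: BLOSUM62 (cutoff > 0), EX
#'   (cutoff > 2; synthetic stand-in, see [ex_matrix()]), delta_V and
#'   delta_P (cutoff > 3).
#' @export
conservation_matrices <- function() {
  list(BLOSUM62 = blosum62_matrix(), EX = ex_matrix(),
       delta_V = delta_v_matrix(), delta_P = delta_p_matrix())
}
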