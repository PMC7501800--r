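# Independent oracles used across the suite. These deliberately share no
# code with the package implementation paths they check.

# Optimal global affine-gap alignment score by dynamic programming over the
# three-state (match / gap-in-hit / gap-in-query) recursion. A gap run of
# length L costs open + L * ext.
gotoh_score <- function(a, b, scores, open, ext) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best_prev <- max(M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- best_prev + scores[x[i], y[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                           X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                           X[i + 1, j] - open - ext,
                           Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force enumeration of every monotone global alignment (no gap-vs-gap
# columns), scoring gap runs exactly; exponential, for tiny inputs only.
enum_align_score <- function(a, b, scores, open, ext) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y))
      best <- max(best, scores[x[i], y[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(x)) {
      pen <- if (prev == "X") ext else open + ext
      best <- max(best, -pen + rec(i + 1, j, "X"))
    }
    if (j <= length(y)) {
      pen <- if (prev == "Y") ext else open + ext
      best <- max(best, -pen + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}

# Reference chi-squared on a 2x2 table (R's own implementation)
chisq_oracle <- function(a, b, c, d, correct = FALSE) {
  suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                     correct = correct))
}

# Exact per-score pair counts over all 380 ordered standard-residue pairs
pair_score_enumeration <- function(m) {
  sc <- integer(0)
  for (a in AA20) for (b in setdiff(AA20, a))
    sc <- c(sc, score_substitution(m, a, b))
  table(sc)
}
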