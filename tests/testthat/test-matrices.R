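test_that("load_matrix validates structure and rejects bad files", {
  p <- write_matrix_tsv(identity_norm_values())
  m <- load_matrix(p, "normalized", name = "identity")
  expect_s3_class(m, "aa_norm_matrix")
  expect_equal(min(m$values), 0)
  expect_equal(max(m$values), 1)

  v <- identity_norm_values()
  v["A", "R"] <- 0.2; v["R", "A"] <- 0.3
  expect_error(load_matrix(write_matrix_tsv(v), "normalized"), "asymmetric")

  v <- identity_norm_values()[-1, -1]
  expect_error(load_matrix(write_matrix_tsv(v), "normalized"), "missing amino acid")

  v <- identity_norm_values()
  v["A", "A"] <- 1.5
  expect_error(load_matrix(write_matrix_tsv(v), "normalized"), "\\[0, 1\\]")

  v <- identity_norm_values()
  storage.mode(v) <- "character"; v["C", "C"] <- "oops"
  expect_error(load_matrix(write_matrix_tsv(v), "normalized"), "non-numeric")
})

test_that("bundled normalized matrices are symmetric with extrema 0 and 1", {
  for (f in c("ex_synthetic_normalized.tsv", "delta_v_normalized.tsv",
              "delta_p_normalized.tsv")) {
    m <- load_matrix(system.file("extdata", f, package = "aacons"), "normalized")
    expect_identical(dim(m$values), c(20L, 20L))
    expect_true(isSymmetric(unname(m$values)))
    expect_equal(min(m$values), 0)
    expect_equal(max(m$values), 1)
  }
})

test_that("bundled BLOSUM62 equals the canonical NCBI matrix", {
  b <- blosum62_matrix()
  ref <- local({ data(BLOSUM62, package = "Biostrings", envir = environment())
                 BLOSUM62[AA20, AA20] })
  expect_identical(unname(b$scores), unname(ref))
  expect_type(b$scores, "integer")
  expect_identical(b$conservative_cutoff, 0L)
})

test_that("delta_from_scale complements the normalized property change", {
  toy <- delta_from_scale(c(A = 0, G = 1, W = 3), "toy")
  expect_equal(toy$values["A", "G"], 2 / 3)  # Delta = 1/3
  expect_equal(toy$values["A", "W"], 0)      # maximal property difference
  expect_equal(unname(diag(toy$values)), rep(1, 3))
  expect_error(delta_from_scale(c(A = 2, G = 2, W = 2)), "equal")

  # orientation: conservativeness strictly decreases as |dp| increases
  sc <- aacons:::read_property_scales()$volume
  dv <- delta_from_scale(sc, "delta_V")
  d <- abs(outer(sc, sc, "-"))
  ut <- upper.tri(d)
  ord <- order(d[ut])
  expect_true(all(diff(dv$values[ut][ord]) <= 1e-12))
  expect_equal(dv$values[ut], 1 - d[ut] / max(d))
})

test_that("integer rescaling maps [0,1] onto [-5,+5] with half-away ties", {
  v <- identity_norm_values()
  v["A", "R"] <- v["R", "A"] <- 0.72  # 10v - 5 = 2.2
  v["N", "D"] <- v["D", "N"] <- 0.55  # tie at 0.5 -> 1
  v["C", "Q"] <- v["Q", "C"] <- 0.45  # tie at -0.5 -> -1
  s <- rescale_to_integer(aacons:::new_norm_matrix("toy", v), 0L)
  expect_equal(unname(diag(s$scores)), rep(5, 20))   # v = 1 -> +5
  expect_equal(s$scores["A", "C"], -5)               # v = 0 -> -5
  expect_equal(s$scores["A", "R"], 2)
  expect_equal(s$scores["N", "D"], 1)
  expect_equal(s$scores["C", "Q"], -1)
  expect_error(rescale_to_integer(s, 0L), "normalized")
})

test_that("substitution scoring is symmetric and rejects non-substitutions", {
  b <- blosum62_matrix()
  expect_identical(score_substitution(b, "F", "Y"), 3L)
  for (m in conservation_matrices()) {
    pairs <- expand.grid(a = AA20, b = AA20, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    expect_identical(score_substitution(m, pairs$a, pairs$b),
                     score_substitution(m, pairs$b, pairs$a))
  }
  expect_error(score_substitution(b, "L", "L"), "not a substitution")
  expect_error(score_substitution(b, "E", "X"), "nonstandard")
  expect_error(is_conservative(b, "E", "*"), "nonstandard")
})

test_that("conservative predicate is strictly greater-than the cutoff", {
  for (m in conservation_matrices()) {
    pairs <- expand.grid(a = AA20, b = AA20, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    sc <- score_substitution(m, pairs$a, pairs$b)
    cons <- is_conservative(m, pairs$a, pairs$b)
    expect_identical(cons, sc > m$conservative_cutoff)
    at_cut <- sc == m$conservative_cutoff
    if (any(at_cut)) expect_false(any(cons[at_cut]))
    # symmetry of the predicate over all ordered pairs
    expect_identical(cons, is_conservative(m, pairs$b, pairs$a))
  }
})

test_that("the four analysis matrices carry their documented cutoffs", {
  ms <- conservation_matrices()
  expect_identical(vapply(ms, function(m) m$conservative_cutoff, 0L),
                   c(BLOSUM62 = 0L, EX = 2L, delta_V = 3L, delta_P = 3L))
  for (m in ms[c("EX", "delta_V", "delta_P")]) {
    off <- m$scores[row(m$scores) != col(m$scores)]
    expect_gte(min(off), -5)
    expect_lte(max(off), 5)
  }
})
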