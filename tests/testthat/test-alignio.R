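test_that("read_fasta parses ids, flags ambiguity, rejects bad input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "ACDEFGHIKL", ">p2", "MNPQRSTVWYACD"), f)
  x <- read_fasta(f)
  expect_identical(names(x), c("p1", "p2"))
  expect_identical(unname(Biostrings::width(x)), c(10L, 13L))
  expect_identical(S4Vectors::mcols(x)$description[1], "some description")
  expect_false(any(S4Vectors::mcols(x)$has_ambiguity))

  writeLines(c(">p1", "ACDXFG"), f)
  expect_message(x <- read_fasta(f), "ambiguity")
  expect_true(S4Vectors::mcols(x)$has_ambiguity[1])

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">p1", "ACD", ">p1", "ACD"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">p1", "AC1D"), f)
  expect_error(read_fasta(f), "illegal")
})

test_that("identical sequences align gap-free at 100% identity", {
  a <- "MKVLAWQERTYIPASDFGH"
  aln <- global_align(a, a)
  st <- alignment_stats(aln)
  expect_equal(st$n_gap_columns, 0)
  expect_equal(st$percent_identity, 100)
  b <- blosum62_matrix()
  expect_equal(aln$score,
               sum(diag(b$scores)[match(strsplit(a, "")[[1]], AA20)]))
  # optimality bound: a low-similarity pair never beats self-alignment
  rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  expect_lte(global_align(a, rev_a)$score, aln$score)
})

test_that("aligner score equals the exhaustive-enumeration oracle on tiny pairs", {
  b <- blosum62_matrix()
  set.seed(101)
  letters4 <- c("A", "C", "D", "E")
  for (i in 1:25) {
    a <- paste(sample(letters4, sample(2:4, 1), replace = TRUE), collapse = "")
    s <- paste(sample(letters4, sample(2:4, 1), replace = TRUE), collapse = "")
    for (pen in list(c(11, 1), c(3, 1))) {
      enum <- enum_align_score(a, s, b$scores, pen[1], pen[2])
      dp <- gotoh_score(a, s, b$scores, pen[1], pen[2])
      expect_equal(dp, enum)  # DP oracle itself is exhaustive-equivalent
      got <- global_align(a, s, gap_open = pen[1], gap_extend = pen[2])$score
      expect_equal(got, enum)
    }
  }
})

test_that("aligner matches the DP oracle on random longer pairs", {
  b <- blosum62_matrix()
  set.seed(202)
  for (i in 1:50) {
    a <- paste(sample(AA20, sample(3:8, 1), replace = TRUE), collapse = "")
    s <- paste(sample(AA20, sample(3:8, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, s, gap_open = 11, gap_extend = 1)$score,
                 gotoh_score(a, s, b$scores, 11, 1))
  }
})

test_that("alignment statistics follow the BLAST span convention", {
  st <- alignment_stats(make_aln(strrep("A", 10), strrep("A", 10)))
  expect_equal(st[, c("span", "n_match", "percent_identity")],
               data.frame(span = 10L, n_match = 10L, percent_identity = 100))

  # 100 columns, 99 matches, 1 mismatch
  q <- strrep("A", 100)
  s <- paste0(strrep("A", 99), "C")
  expect_equal(alignment_stats(make_aln(q, s))$percent_identity, 99)

  # 100 columns, 98 matches, 2 gap columns: denominator includes the gaps
  q <- paste0(strrep("A", 98), "CC")
  s <- paste0(strrep("A", 98), "--")
  st <- alignment_stats(make_aln(q, s))
  expect_equal(st$n_gap_columns, 2)
  expect_equal(st$percent_identity, 98)
  expect_equal(st$n_match + st$n_mismatch + st$n_gap_columns, st$span)

  expect_error(alignment_stats(make_aln("A-C", "--C")), "gap-vs-gap")
})

test_that("alignment tables reconstruct, warn on stale pident, and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tpident\tlength\tgaps\tqlen\tqseq\tsseq",
               "q1\th1\t80\t5\t1\t4\tACD-F\tACDEF"), f)
  out <- read_alignment_table(f)
  st <- out$stats
  expect_equal(st[, c("span", "n_match", "n_gap_columns")],
               data.frame(span = 5L, n_match = 4L, n_gap_columns = 1L))

  writeLines(c("qseqid\tsseqid\tpident\tlength\tgaps\tqlen\tqseq\tsseq",
               "q1\th1\t99\t10\t0\t10\tAAAAAAAAAC\tAAAAAAAAAA"), f)
  expect_warning(out <- read_alignment_table(f), "recomputed")
  expect_equal(out$stats$percent_identity, 90)

  writeLines(c("qseqid\tsseqid\tpident\tlength\tgaps\tqlen\tqseq\tsseq",
               "q1\th1\t80\t5\t1\t4\tACD-F\tACDEFG"), f)
  expect_error(read_alignment_table(f), "unequal length")

  alns <- list(make_aln("ACD-F", "ACDEF", "q1", "h1"),
               make_aln("MKVL", "MKIL", "q2", "h2"))
  p <- tempfile(fileext = ".tsv")
  write_alignment_table(alns, p)
  back <- read_alignment_table(p)
  expect_identical(vapply(back$alignments, function(a) a$qseq, ""),
                   vapply(alns, function(a) a$qseq, ""))
  expect_identical(vapply(back$alignments, function(a) a$sseq, ""),
                   vapply(alns, function(a) a$sseq, ""))
})

test_that("best-hit selection ranks by score, identity, then hit id", {
  a1 <- make_aln("ACDEF", "ACDEF", hit_id = "h1", score = 120)
  a2 <- make_aln("ACDEF", "ACDEG", hit_id = "h2", score = 80)
  expect_identical(pick_best_hit(list(a2))$hit_id, "h2")
  expect_identical(pick_best_hit(list(a1, a2))$hit_id, "h1")
  # equal scores: higher identity wins
  a3 <- make_aln("ACDEF", "ACDEG", hit_id = "h3", score = 100)  # 80%
  a4 <- make_aln("ACDEF", "ACDEF", hit_id = "h4", score = 100)  # 100%
  expect_identical(pick_best_hit(list(a3, a4))$hit_id, "h4")
  # equal score and identity: lexicographic hit id
  a5 <- make_aln("ACDEF", "ACDEF", hit_id = "hb", score = 100)
  a6 <- make_aln("ACDEF", "ACDEF", hit_id = "ha", score = 100)
  expect_identical(pick_best_hit(list(a5, a6))$hit_id, "ha")
  expect_error(pick_best_hit(list()), "no candidate")
})

test_that("isoform filtering keeps the longest per gene, ties by id", {
  seqs <- Biostrings::AAStringSet(c(g1a = "ACDEFGH", g1b = "ACD",
                                    g2a = "MKVL", g2b = "MKIL"))
  kept <- keep_longest_isoform(seqs, gene = c("g1", "g1", "g2", "g2"))
  expect_identical(names(kept), c("g1a", "g2a"))
})
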