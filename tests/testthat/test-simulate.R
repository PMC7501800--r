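test_that("replacement kernel normalizes exp(beta * score) over alternatives", {
  b <- blosum62_matrix()
  k0 <- replacement_kernel(0, b)
  expect_equal(unname(k0$P["A", setdiff(AA20, "A")]), rep(1 / 19, 19))
  expect_equal(unname(diag(k0$P)), rep(0, 20))

  # beta = 1, from L: direct 19-term normalization oracle
  k1 <- replacement_kernel(1, b)
  w <- exp(1 * b$scores["L", setdiff(AA20, "L")])
  expect_equal(k1$P["L", setdiff(AA20, "L")], w / sum(w))

  # large beta concentrates on the max-score partner(s)
  k9 <- replacement_kernel(9, b)
  best <- names(which.max(b$scores["F", setdiff(AA20, "F")]))
  expect_gt(k9$P["F", best], 0.99)

  expect_error(replacement_kernel(1, b, allowed = "A"), ">= 2")
  expect_error(replacement_kernel(1, b, allowed = c("A", "J")), "alphabet")
})

test_that("sequence evolution applies consistent Poisson event chains", {
  k <- replacement_kernel(0, blosum62_matrix())
  set.seed(41)
  anc <- sample(AA20, 200, replace = TRUE)

  out0 <- evolve_sequence(anc, 0, k)
  expect_identical(out0$descendant, anc)
  expect_identical(out0$n_events, 0L)
  expect_length(out0$events, 0)

  out <- evolve_sequence(anc, 0.5, k)
  for (site in names(out$events)) {
    chain <- out$events[[site]]
    i <- as.integer(site)
    expect_identical(unname(chain[1, "from"]), anc[i])
    if (nrow(chain) > 1)
      expect_identical(unname(chain[-1, "from"]), unname(chain[-nrow(chain), "to"]))
    expect_identical(out$descendant[i], unname(chain[nrow(chain), "to"]))
  }
  # sites without events are unchanged; mismatches never exceed events
  untouched <- setdiff(seq_along(anc), as.integer(names(out$events)))
  expect_identical(out$descendant[untouched], anc[untouched])
  expect_lte(sum(out$descendant != anc), out$n_events)
})

test_that("realized mismatch counts track the Poisson expectation", {
  k <- replacement_kernel(0, blosum62_matrix())
  set.seed(42)
  n <- 10000; d <- 0.01
  anc <- sample(AA20, n, replace = TRUE)
  out <- evolve_sequence(anc, d, k)
  # events are Poisson(n*d); mismatches are a thinned subset
  expect_lt(abs(out$n_events - n * d), 3 * sqrt(n * d))
  expect_lte(sum(out$descendant != anc), out$n_events)
  # back-mutation leaves no observed mismatch despite events: construct one
  k2 <- replacement_kernel(0, blosum62_matrix(), allowed = c("K", "R"))
  chain <- evolve_sequence("K", 0, k2)
  expect_identical(chain$descendant, "K")
})

test_that("ortholog simulation is seed-deterministic and class-consistent", {
  s1 <- simulate_ortholog_set(2, 2, seed = 7)
  s2 <- simulate_ortholog_set(2, 2, seed = 7)
  expect_identical(s1, s2)

  fast_only <- simulate_ortholog_set(0, 3, seed = 8)
  expect_identical(unique(fast_only$truth$class), "fast")

  cfg <- sim_config(500, 0.05, 2)
  expect_error(simulate_ortholog_set(1, 1, cfg_slow = cfg,
                                     cfg_fast = sim_config(500, 0.01, 0)),
               "lower branch divergence")
  expect_error(simulate_ortholog_set(1, 1, cfg_slow = sim_config(500, 0.001, 0),
                                     cfg_fast = sim_config(500, 0.01, 1)),
               "bias")
})

test_that("slow-class pairs land above 99% identity, fast near their target", {
  sim <- simulate_ortholog_set(5, 5, seed = 9)
  idents <- vapply(sim$pairs, function(p) {
    alignment_stats(global_align(p$query, p$hit))$percent_identity
  }, 0)
  expect_true(all(idents[sim$truth$class == "slow"] > 98.5))
  expect_gt(mean(idents[sim$truth$class == "slow"] > 99), 0.5)
  expect_true(all(abs(idents[sim$truth$class == "fast"] - 93.2) < 4))
})

test_that("higher divergence never raises expected identity (seeded batches)", {
  k <- replacement_kernel(0, blosum62_matrix())
  set.seed(10)
  mean_ident <- vapply(c(0.004, 0.02, 0.08), function(d) {
    mean(vapply(1:5, function(i) {
      anc <- sample(AA20, 800, replace = TRUE)
      a <- evolve_sequence(anc, d, k)$descendant
      b <- evolve_sequence(anc, d, k)$descendant
      mean(a == b)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ident) < 0))
})

test_that("SNP simulation respects spectra, strata and determinism", {
  empty <- simulate_snp_table(0, "fast")
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("variant_id", "protein_id", "ref_aa", "alt_aa", "af", "maf"))

  all_common <- simulate_snp_table(200, "fast", maf_spectrum = function(k) rep(0.2, k),
                                   seed = 13)
  s <- stratify_by_maf(all_common)
  expect_identical(nrow(s$gt_001), 200L)
  expect_identical(nrow(s$gt_01), 200L)
  expect_identical(nrow(s$gt_05), 200L)
  expect_identical(nrow(s$rare), 0L)

  expect_identical(simulate_snp_table(50, "slow", seed = 14),
                   simulate_snp_table(50, "slow", seed = 14))

  # stratum-dependent bias: rare fast variants are the least conservative
  b <- blosum62_matrix()
  snp <- simulate_snp_table(8000, "fast", seed = 15)
  st <- stratify_by_maf(snp)
  expect_lt(conservative_fraction(st$rare, b)$fraction,
            conservative_fraction(st$gt_001, b)$fraction)
})

test_that("exact kernel expectation matches enumeration and is monotone in beta", {
  b <- blosum62_matrix()
  k0 <- replacement_kernel(0, b)
  n_cons <- sum(vapply(AA20, function(a)
    sum(b$scores[a, setdiff(AA20, a)] > 0), 0L))
  expect_equal(expected_conservative_fraction(k0, m = b), n_cons / 380)

  # all-conservative alphabet: F/Y/W are mutually conservative under BLOSUM62
  k_fyw <- replacement_kernel(0, b, allowed = c("F", "Y", "W"))
  expect_equal(expected_conservative_fraction(k_fyw, m = b), 1)

  betas <- c(0, 0.5, 1, 2, 4)
  fr <- vapply(betas, function(beta)
    expected_conservative_fraction(replacement_kernel(beta, b), m = b), 0)
  expect_true(all(diff(fr) > 0))
})

test_that("trio simulation restricted to k letters stays on its site alphabets", {
  k <- replacement_kernel(0, blosum62_matrix())
  tr <- simulate_trio(300, 2, k, site_alphabet_size = 2, seed = 16)
  rows <- do.call(rbind, strsplit(unname(tr$taxa), ""))
  anc <- strsplit(tr$ancestor, "")[[1]]
  # with k = 2 every column holds at most 2 distinct residues incl. ancestor
  n_distinct <- apply(rbind(rows, anc), 2, function(col) length(unique(col)))
  expect_true(all(n_distinct <= 2))
})
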