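# Substitution-process simulator: generates ortholog pairs/trios and
# missense variant tables with controlled divergence and conservativeness
# bias, so every stage of the analysis can be exercised without external
# data. Per-site event counts are Poisson (not a single Bernoulli draw), so
# repeated mutation, back-mutation and saturation are all realizable.

#' Replacement kernel biased toward conservative changes
#'
#' Conditional distribution of the replacing residue: P(b | a) is
#' proportional to exp(beta * s(a, b)) over b != a in the allowed alphabet,
#' where s is the matrix score. beta = 0 gives the uniform kernel over the
#' alternatives; larger beta concentrates mass on the highest-scoring
#' (most conservative) partners.
#'
#' @param beta Conservativeness bias (real; 0 = unbiased).
#' @param m An `aa_subst_matrix` supplying the scores.
#' @param allowed Residue alphabet (>= 2 letters, subset of the matrix
#'   alphabet; default the full 20).
#' @return A `replacement_kernel`: row-stochastic matrix `P` (rows = from,
#'   columns = to, zero diagonal) plus `beta`, `matrix_name`, `alphabet`.
#' @export
replacement_kernel <- function(beta, m = blosum62_matrix(), allowed = m$alphabet) {
  if (length(allowed) < 2L) stop("replacement kernel needs >= 2 allowed residues")
  bad <- setdiff(allowed, m$alphabet)
  if (length(bad)) stop("residue(s) outside matrix alphabet: ", paste(bad, collapse = ", "))
  s <- m$scores[allowed, allowed, drop = FALSE]
  w <- exp(beta * s)
  diag(w) <- 0
  P <- w / rowSums(w)
  structure(list(P = P, beta = beta, matrix_name = m$name, alphabet = allowed),
            class = "replacement_kernel")
}

#' @export
print.replacement_kernel <- function(x, ...) {
  cat(sprintf("Replacement kernel: beta = %g on '%s' scores, %d-letter alphabet\n",
              x$beta, x$matrix_name, length(x$alphabet)))
  invisible(x)
}

# vectorized single replacement draw: one new residue per element of `from`
sample_replacement <- function(kernel, from) {
  out <- character(length(from))
  for (a in unique(from)) {
    idx <- which(from == a)
    out[idx] <- sample(kernel$alphabet, length(idx), replace = TRUE,
                       prob = kernel$P[a, ])
  }
  out
}

#' Evolve a sequence under the Poisson substitution process
#'
#' Each site receives a Poisson(divergence) number of mutation events,
#' applied sequentially through the replacement kernel; the full per-site
#' event chains are returned, so back-mutations and repeated hits are
#' observable even when they leave no sequence difference.
#'
#' @param ancestor Character vector of residues (or a single string).
#' @param divergence Expected substitution events per site on this branch
#'   (>= 0).
#' @param kernel A `replacement_kernel`; every ancestor residue must lie in
#'   its alphabet.
#' @return List with `descendant` (character vector), `events` (list, one
#'   two-column `from`/`to` matrix per site with at least one event, named
#'   by site index) and `n_events`.
#' @export
evolve_sequence <- function(ancestor, divergence, kernel) {
  if (length(ancestor) == 1L && nchar(ancestor[1L]) > 1L)
    ancestor <- strsplit(ancestor, "")[[1]]
  if (divergence < 0) stop("divergence must be >= 0")
  stopifnot(all(ancestor %in% kernel$alphabet))
  n <- length(ancestor)
  counts <- rpois(n, divergence)
  desc <- ancestor
  events <- list()
  for (i in which(counts > 0L)) {
    res <- desc[i]
    chain <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
    for (k in seq_len(counts[i])) {
      new <- sample_replacement(kernel, res)
      chain <- rbind(chain, c(res, new))
      res <- new
    }
    desc[i] <- res
    events[[as.character(i)]] <- chain
  }
  list(descendant = desc, events = events, n_events = sum(counts))
}

uniform_composition <- function(alphabet) setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)

sample_ancestor <- function(n, composition) {
  sample(names(composition), n, replace = TRUE, prob = composition)
}

#' Simulation configuration for one protein class
#'
#' @param length Protein length in residues.
#' @param divergence Expected substitution events per site per branch.
#' @param beta Conservativeness bias of the replacement kernel.
#' @param matrix Scoring matrix driving the kernel (default BLOSUM62).
#' @param composition Named amino-acid frequencies summing to 1 (default
#'   uniform over the matrix alphabet).
#' @return A `sim_config` list.
#' @export
sim_config <- function(length, divergence, beta, matrix = blosum62_matrix(),
                       composition = NULL) {
  if (divergence < 0) stop("divergence must be >= 0")
  composition <- composition %||% uniform_composition(matrix$alphabet)
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  structure(list(length = as.integer(length), divergence = divergence,
                 beta = beta, matrix = matrix, composition = composition),
            class = "sim_config")
}

#' Simulate a set of ortholog pairs for slow and fast protein classes
#'
#' Each protein draws an ancestral sequence from the class composition and
#' evolves two descendant branches (query and hit species) independently at
#' the class divergence under the class replacement kernel. Defaults realize
#' the contrast the rate analysis targets: slow proteins are long (1500 aa)
#' with divergence 0.004 events/site/branch and strong conservative bias
#' (beta = 2), landing above 99% identity; fast proteins are short (450 aa)
#' with divergence 0.035 and no bias (beta = 0), landing near 93% identity.
#'
#' @param n_slow,n_fast Number of proteins per class.
#' @param cfg_slow,cfg_fast `sim_config` objects; slow must be the less
#'   diverged and at-least-as-biased class.
#' @param seed Optional integer seed for bit-identical output.
#' @return List with `pairs` (list of `list(query_id, hit_id, query, hit)`
#'   residue strings) and `truth` (data.frame: protein_id, class, length,
#'   divergence, beta, n_events_query, n_events_hit).
#' @export
simulate_ortholog_set <- function(n_slow, n_fast,
                                  cfg_slow = sim_config(1500, 0.004, 2),
                                  cfg_fast = sim_config(450, 0.035, 0),
                                  seed = NULL) {
  if (cfg_slow$divergence >= cfg_fast$divergence)
    stop("slow class must have lower branch divergence than fast class")
  if (cfg_slow$beta < cfg_fast$beta)
    stop("slow class must have conservativeness bias >= fast class")
  if (!is.null(seed)) set.seed(seed)
  classes <- c(rep("slow", n_slow), rep("fast", n_fast))
  pairs <- vector("list", length(classes))
  truth <- vector("list", length(classes))
  kernels <- list(slow = replacement_kernel(cfg_slow$beta, cfg_slow$matrix),
                  fast = replacement_kernel(cfg_fast$beta, cfg_fast$matrix))
  for (i in seq_along(classes)) {
    cfg <- if (classes[i] == "slow") cfg_slow else cfg_fast
    pid <- sprintf("P%04d_%s", i, classes[i])
    anc <- sample_ancestor(cfg$length, cfg$composition)
    q <- evolve_sequence(anc, cfg$divergence, kernels[[classes[i]]])
    h <- evolve_sequence(anc, cfg$divergence, kernels[[classes[i]]])
    pairs[[i]] <- list(query_id = paste0(pid, "_query"),
                       hit_id = paste0(pid, "_hit"),
                       query = paste(q$descendant, collapse = ""),
                       hit = paste(h$descendant, collapse = ""))
    truth[[i]] <- data.frame(protein_id = pid, class = classes[i],
                             length = cfg$length, divergence = cfg$divergence,
                             beta = cfg$beta, n_events_query = q$n_events,
                             n_events_hit = h$n_events,
                             stringsAsFactors = FALSE)
  }
  list(pairs = pairs, truth = do.call(rbind, truth))
}

#' Simulate a three-taxon alignment (star topology)
#'
#' One ancestral sequence evolves three independent branches at the same
#' divergence; taxa A and B are the focal pair and O the outgroup. With a
#' per-site alphabet restriction, each site is confined to a random subset
#' of residues, modelling sites that accommodate only a few residues at
#' saturation equilibrium.
#'
#' @param n_sites Alignment length.
#' @param divergence Expected events per site per branch.
#' @param kernel A `replacement_kernel` (its alphabet bounds the site
#'   alphabets).
#' @param site_alphabet_size Optional integer k (2..alphabet size): each
#'   site evolves on its own random k-letter alphabet. Default: full kernel
#'   alphabet at every site.
#' @param seed Optional integer seed.
#' @return List with `taxa` (named character vector A/B/O of aligned
#'   sequences), `ancestor`, and `n_events` per taxon.
#' @export
simulate_trio <- function(n_sites, divergence, kernel,
                          site_alphabet_size = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ab <- kernel$alphabet
  if (is.null(site_alphabet_size)) {
    anc <- sample(ab, n_sites, replace = TRUE)
    branches <- lapply(1:3, function(i) evolve_sequence(anc, divergence, kernel))
    seqs <- vapply(branches, function(b) paste(b$descendant, collapse = ""), "")
    nev <- vapply(branches, function(b) b$n_events, 0L)
  } else {
    k <- as.integer(site_alphabet_size)
    if (k < 2L || k > length(ab)) stop("site_alphabet_size must be in [2, alphabet size]")
    m <- structure(list(name = kernel$matrix_name, alphabet = ab,
                        scores = NULL), class = "aa_subst_matrix")
    site_sets <- replicate(n_sites, sample(ab, k), simplify = FALSE)
    anc <- vapply(site_sets, function(s) sample(s, 1L), "")
    # cache one restricted kernel per distinct letter set
    kcache <- new.env(parent = emptyenv())
    kernel_for <- function(s) {
      key <- paste(sort(s), collapse = "")
      if (is.null(kcache[[key]])) {
        sub <- kernel$P[s, s, drop = FALSE]
        # renormalize the full kernel restricted to the site alphabet
        P <- sub / rowSums(sub)
        kcache[[key]] <- structure(list(P = P, beta = kernel$beta,
                                        matrix_name = kernel$matrix_name,
                                        alphabet = s),
                                   class = "replacement_kernel")
      }
      kcache[[key]]
    }
    seqs <- character(3); nev <- integer(3)
    desc <- matrix("", 3, n_sites)
    counts <- matrix(rpois(3L * n_sites, divergence), 3, n_sites)
    for (t in 1:3) {
      res <- anc
      for (i in which(counts[t, ] > 0L)) {
        kk <- kernel_for(site_sets[[i]])
        r <- res[i]
        for (e in seq_len(counts[t, i])) r <- sample_replacement(kk, r)
        res[i] <- r
      }
      desc[t, ] <- res
      nev[t] <- sum(counts[t, ])
    }
    seqs <- apply(desc, 1, paste, collapse = "")
  }
  list(taxa = setNames(seqs, c("A", "B", "O")),
       ancestor = paste(anc, collapse = ""),
       n_events = setNames(nev, c("A", "B", "O")))
}

#' Simulate a missense variant table
#'
#' Draws reference residues from the composition and alternate residues
#' through a replacement kernel whose bias depends on the variant's MAF
#' stratum (rare: MAF < 0.001; common: MAF > 0.001), emulating the
#' population-genetic structure in which rare variants in fast evolving
#' proteins are the least conservative. MAF values are drawn log-uniformly
#' on \[1e-5, 0.5\] by default; the reported AF is the MAF or its complement
#' with equal probability. Class defaults: slow beta (rare 1, common 1.5);
#' fast beta (rare 0, common 0.5).
#'
#' @param n Number of variants (0 allowed: empty table).
#' @param class `"slow"` or `"fast"`; prefixes protein ids and sets default
#'   stratum biases.
#' @param beta_by_stratum Named numeric `c(rare =, common =)`.
#' @param m Scoring matrix driving the kernel (default BLOSUM62).
#' @param maf_spectrum Function n -> n MAF values in \[0, 0.5\].
#' @param composition Named residue frequencies (default uniform).
#' @param n_proteins Number of distinct protein ids to spread variants over.
#' @param seed Optional integer seed.
#' @return Missense variant `data.frame` (`variant_id, protein_id, ref_aa,
#'   alt_aa, af, maf`), compatible with [write_missense_table()].
#' @export
simulate_snp_table <- function(n, class = c("slow", "fast"),
                               beta_by_stratum = NULL,
                               m = blosum62_matrix(),
                               maf_spectrum = function(k) 10^runif(k, -5, log10(0.5)),
                               composition = NULL, n_proteins = 50L,
                               seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  beta_by_stratum <- beta_by_stratum %||%
    (if (class == "slow") c(rare = 1, common = 1.5) else c(rare = 0, common = 0.5))
  if (!all(c("rare", "common") %in% names(beta_by_stratum)))
    stop("beta_by_stratum must name 'rare' and 'common' biases")
  composition <- composition %||% uniform_composition(m$alphabet)
  cols <- c("variant_id", "protein_id", "ref_aa", "alt_aa", "af", "maf")
  if (n == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 6), cols))
    df$af <- numeric(0); df$maf <- numeric(0)
    return(df)
  }
  maf <- maf_spectrum(n)
  stopifnot(all(maf >= 0 & maf <= 0.5))
  stratum <- ifelse(maf < 0.001, "rare", "common")
  ref <- sample_ancestor(n, composition)
  alt <- character(n)
  for (st in c("rare", "common")) {
    idx <- which(stratum == st)
    if (!length(idx)) next
    kern <- replacement_kernel(beta_by_stratum[[st]], m,
                               allowed = names(composition))
    alt[idx] <- sample_replacement(kern, ref[idx])
  }
  af <- ifelse(runif(n) < 0.5, maf, 1 - maf)
  data.frame(variant_id = sprintf("%s_v%06d", class, seq_len(n)),
             protein_id = sprintf("%s_P%03d", class,
                                  sample.int(n_proteins, n, replace = TRUE)),
             ref_aa = ref, alt_aa = alt, af = af, maf = compute_maf(af),
             stringsAsFactors = FALSE)
}

#' Exact conservative fraction expected under a kernel
#'
#' Full-enumeration oracle: sum over ordered residue pairs of
#' pi(a) P(b | a) 1\[s(a, b) > cutoff\], i.e. the probability that a single
#' replacement drawn from the kernel is conservative under matrix `m`.
#'
#' @param kernel A `replacement_kernel`.
#' @param composition Named frequencies over the kernel alphabet (default
#'   uniform).
#' @param m An `aa_subst_matrix` (may differ from the kernel's own matrix).
#' @return Numeric scalar in \[0, 1\].
#' @export
expected_conservative_fraction <- function(kernel, composition = NULL,
                                           m = blosum62_matrix()) {
  ab <- kernel$alphabet
  composition <- composition %||% uniform_composition(ab)
  stopifnot(all(ab %in% names(composition)))
  total <- 0
  for (a in ab) for (b in setdiff(ab, a)) {
    total <- total + composition[[a]] * kernel$P[a, b] *
      (m$scores[a, b] > m$conservative_cutoff)
  }
  total
}

#' Write simulated ortholog pairs as FASTA
#'
#' @param sim Output of [simulate_ortholog_set()].
#' @param path Output FASTA (query and hit records interleaved).
#' @export
write_ortholog_fasta <- function(sim, path) {
  seqs <- unlist(lapply(sim$pairs, function(p)
    setNames(c(p$query, p$hit), c(p$query_id, p$hit_id))))
  write_fasta(seqs, path)
}
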