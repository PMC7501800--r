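---
title: "Scoring conservative amino-acid substitutions across evolutionary rates: methods and design"
author: "aacons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring conservative amino-acid substitutions across evolutionary rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacons)
```

## The question and the model

Between two closely related species, most proteins differ at a handful of
residues. Whether those observed replacements are biochemically mild
("conservative") or drastic carries information about the regime the
protein evolves in: substitutions accumulated slowly under strong
constraint look different from substitutions in proteins whose sites have
been hit repeatedly (mutation saturation), where the residues seen today
are shaped more by what selection tolerates than by mutation history. The
same contrast applies within a population: rare missense variants are
enriched for changes still being purged by selection, whereas common
variants are closer to neutral.

`aacons` operationalizes this as three linked measurements:

1. a **conservativeness score** for every replacement, under four matrices;
2. the **conservative fraction** of pooled replacements, per
   evolutionary-rate bin (fixed differences) or per MAF stratum (standing
   variation), compared by chi-squared;
3. an **overlap-ratio** saturation diagnostic from three-or-more-taxon
   alignments.

## The four matrices

| name | source of values | cutoff | rationale |
|------|------------------|--------|-----------|
| BLOSUM62 | canonical NCBI integer matrix, used raw | > 0 | alignment-derived similarity |
| EX | synthetic exchangeability stand-in (see below) | > 2 | mutagenesis-style exchangeability, free of substitution-probability effects |
| delta_V | side-chain volume scale (Grantham 1974) | > 3 | pure physicochemistry |
| delta_P | side-chain polarity scale (Grantham 1974) | > 3 | pure physicochemistry |

The conservative predicate is strict (`score > cutoff`; equality is
non-conservative) and symmetric. Cutoffs differ per matrix so that each
calls a comparable share of observed changes conservative.

**Delta matrices.** From a property scale $p$,
$\Delta(a,b) = |p(a)-p(b)| / \max_{x,y}|p(x)-p(y)|$ is the normalized
change; we complement it, $c = 1 - \Delta$, *before* integer rescaling, so
that higher scores mean more conservative changes and the strict
greater-than cutoff points in the right direction. Rescaling is
$s = \mathrm{round}(10c - 5)$, mapping $[0,1]$ onto $[-5,+5]$; rounding
ties (…,−0.5, 0.5,…) go **away from zero**, a fixed documented choice since
"nearest integer" alone does not settle ties.

**BLOSUM62** is used as the canonical raw integer matrix (off-diagonal
range −4…3). Because the conservative predicate only asks whether a score
exceeds 0, any clipping of the extreme negative scores would not change a
single conservative/non-conservative call.

**The EX stand-in.** The package's exchangeability-style matrix is a
deterministic synthetic construction — the complement of the mean
normalized pairwise distance in side-chain volume, polarity and
hydropathy, min-max rescaled to $[0,1]$ — bundled as
`ex_synthetic_normalized.tsv` and clearly labelled synthetic. It has the
structural properties the pipeline needs (symmetric, normalized, extrema
exactly 0 and 1, roughly half of changes above its cutoff after rescaling)
but its individual entries are not experimental exchangeability
measurements; conclusions that depend on the specific published EX values
cannot be drawn from it.

## Alignment and its statistics

The internal aligner is global Needleman–Wunsch with affine gaps
(open 11, extend 1 — BLASTP's defaults; a run of length $L$ costs
open + $L$·extend), delegated to `Biostrings::pairwiseAlignment` and
verified in the test suite against an independent exhaustive-enumeration /
three-state DP oracle. Global alignment is an adequate surrogate for
best-hit local alignment here because the analysis consumes near
full-length ortholog pairs; genuinely local BLAST output can be supplied
instead through `read_alignment_table()` (tabular format with aligned
`qseq`/`sseq` strings), in which case identity is recomputed from the
columns and trusted over the file's `pident` (warning on > 0.05
disagreement).

Percent identity uses the full alignment span as denominator, gap columns
included (the BLAST convention; the choice matters at the fraction of a
percent level and is applied consistently). Gap columns are counted per
column, not per run. Where several isoforms share a gene,
`keep_longest_isoform()` retains the longest (ties: lexicographically
smallest id). Best-hit selection ranks by score, then identity, then hit
id — fully deterministic.

## Rate classification

Eligibility: query length > 200 aa and identity strictly > 60%. Strata:
long (> 1102 aa) vs short (200–1102 aa); gap-free vs gapped alignments.
Identity bins are upper-inclusive half-open intervals — long: (99,100],
(98,99], (96,98], [87,96]; short: (95,100], (90,95], (80,90], (60,80] — so
a boundary identity (exactly 99, 98, 96, 95, 90, 80) falls in the lower
bin; this edge rule is a package decision, fixed and tested, since interval
membership at the printed bin edges is otherwise ambiguous. Long-stratum
identities below 87 are labelled `out-of-range` rather than forced into a
bin. Identity is carried at full floating precision; nothing is rounded
before binning.

The slow set is (length > 304 aa ∧ identity = 100% ∧ zero gap columns) ∪
(length > 1102 aa ∧ identity > 99%). Requiring the 100% clause to be
gap-free is deliberate: under the span convention an alignment can reach
100% matches over its matched columns while still containing gaps, and a
gapped "perfect" alignment is not a credible slowest-evolving protein.

## Fractions, pooling and tests

Within each (length, gap, bin) cell, substitutions are **pooled across
proteins** and the conservative fraction is the pooled ratio. Pooling (not
averaging per-protein fractions) is the default because the downstream
chi-squared test operates on counts; the per-protein average is available
via `per_protein = TRUE`. The pooled fraction equals the count-weighted
mean of per-protein fractions (an algebraic identity the tests assert).
Columns containing ambiguity codes (B, Z, X, U, O, `*`) cannot be scored by
any matrix and are dropped with a logged count. Zero-substitution cells are
flagged undefined, never reported as 0/0.

Group comparisons use the uncorrected Pearson chi-squared on the 2×2 count
table (df = 1); the Yates correction is available by flag but off by
default, matching the common uncorrected test. Significance tiers for
report annotation: `*` < 0.05, `**` < 0.01, `***` < 0.001. No
multiple-testing correction is applied.

## Missense variants and MAF strata

Variants arrive as a TSV (`variant_id, protein_id, ref_aa, alt_aa, af`) or
as a VCF subset whose INFO carries `REF_AA` (Number=1), `ALT_AA` (Number=A),
`PROTEIN` (Number=1) and a per-ALT frequency field (default `AFR_AF`;
configurable because stratification by a single population is the cleanest
frequency measure and results are expected to be population-robust).
Multi-allelic records are split into one variant per ALT with its own AF —
splitting rather than dropping keeps every annotated allele. MAF =
min(AF, 1−AF). Strata are strict: rare (MAF < 0.001) and nested cumulative
common groups (> 0.001 ⊇ > 0.01 ⊇ > 0.05). A variant with MAF exactly
0.001 satisfies neither strict inequality; it is logged and assigned to no
stratum rather than silently resolved. Slow/fast assignment is by
protein-id membership in the classification's slow-set list.

## The saturation diagnostic

For taxa A, B (focal) and outgroups O: a usable column (no gap/ambiguity in
any consulted row) is mismatched iff A ≠ B, and an overlap site iff some
outgroup differs from both A and B — one substitution on the A–B path
cannot produce that configuration, so an overlap site witnesses ≥ 2
independent events. With several outgroups, *any* qualifying outgroup marks
the site (the single-outgroup rule's natural monotone extension; adding an
outgroup can only keep or raise the overlap count on gap-free data).
Convergent double hits that happen to restore equality with a focal residue
are not separately detected; they are a rarer facet of the same phenomenon.
`saturation_call()` labels an alignment saturated-like at ≥ 2× a
pre-saturation baseline ratio; the empirical 50–60% overlap typically seen
at saturation is context, not a hard threshold. For i.i.d. saturated sites
on a k-letter alphabet the expected ratio is (k−2)/k (0.9 for the full
alphabet), which the simulator reproduces.

## The simulator: what it emulates and what it does not

Sequences evolve by a per-site Poisson event process: each site receives
Poisson(divergence) mutation events per branch, applied sequentially
through a replacement kernel
$P(b \mid a) \propto \exp(\beta \, s(a,b))$ over the allowed alphabet.
Poisson event counts (rather than one Bernoulli substitution per site) make
back-mutation, repeated hits, doublet outcomes and saturation all
realizable. β = 0 is the uniform kernel; larger β biases replacements
toward conservative partners. `expected_conservative_fraction()` gives the
exact single-replacement expectation by full enumeration and serves as the
calibration oracle.

Default study conditions (fixed once, used by the validation suite):

* **slow class**: length 1500 aa, divergence 0.004 events/site/branch,
  β = 2 — two branches give expected identity ≈ e^(−0.008) ≈ 99.2%, inside
  the > 99% long-stratum bin;
* **fast class**: length 450 aa, divergence 0.035, β = 0 — identity
  ≈ 93%, the 90–95 short-stratum bin;
* **SNP generator**: MAF log-uniform on [10⁻⁵, 0.5]; stratum-dependent
  bias β(rare)=1, β(common)=1.5 for the slow class and β(rare)=0,
  β(common)=0.5 for the fast class, so that common variants are more
  conservative than rare ones and slow beats fast in every stratum — the
  qualitative structure the analysis is designed to detect. The kernel is
  driven by BLOSUM62 scores; by the exact-expectation oracle this bias
  separates the classes under *all four* scoring matrices (the smallest
  analytic margin is delta_V: 0.50 vs 0.28).

Composition is uniform by default (real proteome composition is a config
option) to keep the enumeration oracles exact and simple. Site-restricted
alphabets (each site confined to k residues) model sites that accommodate
only a few residues at saturation equilibrium.

The generator does **not** emulate: indels (simulated pairs are gap-free,
so gapped-stratum behaviour is exercised only through hand-built and
file-based fixtures), codon structure and mutation-rate heterogeneity
(transitions/transversions, CpG), linkage or demography behind the allele
frequencies, site-to-site rate variation within a protein, or epistasis.
Passing the end-to-end tests therefore shows the pipeline correctly
recovers a planted conservativeness signal of realistic magnitude — not
that real proteomes contain such a signal.

## Numerical and validation choices

* Matrix files are validated strictly: missing residues, non-numeric
  cells, normalized values outside [0,1], or asymmetry beyond 1e−9 are
  errors; nothing is silently symmetrized or clipped.
* Identity exactly 100% is tested with a 1e−9 floating tolerance.
* Determinism: simulations are bit-identical under a fixed seed; the
  orchestrators (`run_fixed_analysis()`, `run_snp_analysis()`) write
  byte-identical outputs on rerun and stamp every run with an MD5 config
  hash in the manifest.
* Validation problem sizes: the aligner is checked against an exhaustive
  oracle on 200 random pairs of length ≤ 8; chi-squared against the
  reference implementation on 1000 random tables to 1e−10; kernel
  calibration with 10,000 draws per (matrix, β) against the binomial 99%
  interval; the slow-vs-fast recovery on 100 simulated proteome sets of
  6 + 6 proteins; overlap-ratio convergence on 10,000-site trios at 5
  events/site/branch. These sizes give comfortable statistical resolution
  for each check while keeping the suite quick on a laptop.

## Known limitations

* The EX stand-in is structural, not the published exchangeability data.
* The aligner's traceback tie-break among co-optimal alignments is the
  alignment library's deterministic choice; scores and all downstream
  statistics are unaffected, but co-optimal gap placements could differ
  from another implementation's.
* The package consumes missense annotation; it does not call consequences
  from transcripts.
* Between-species inference of which lineage carries a change (ancestral
  state) is out of scope; substitutions are unordered pairs.
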