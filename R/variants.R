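# Missense variant ingestion (TSV and a documented VCF INFO mini-dialect),
# minor-allele-frequency derivation and stratification, and the
# slow-vs-fast conservative-fraction report.

#' Minor allele frequency from alternative allele frequency
#'
#' MAF = min(AF, 1 - AF), folding the alternative allele frequency onto
#' \[0, 0.5\].
#'
#' @param af Numeric vector of alternative allele frequencies in \[0, 1\].
#' @return Numeric vector of MAFs.
#' @export
compute_maf <- function(af) {
  if (any(!is.finite(af)) || any(af < 0 | af > 1))
    stop("allele frequencies must lie in [0, 1]")
  pmin(af, 1 - af)
}

validate_variants <- function(df, origin) {
  bad <- setdiff(unique(c(df$ref_aa, df$alt_aa)), AA20)
  if (length(bad))
    stop(origin, ": nonstandard amino acid(s): ", paste(bad, collapse = ", "))
  if (any(df$ref_aa == df$alt_aa))
    stop(origin, ": ref and alt amino acids are identical for ",
         sum(df$ref_aa == df$alt_aa), " row(s); not missense")
  df$maf <- compute_maf(df$af)
  df
}

#' Read a missense variant table
#'
#' Tab-separated file with columns `variant_id, protein_id, ref_aa, alt_aa,
#' af` (alternative allele frequency for one population). MAF is derived as
#' min(AF, 1 - AF). Rows with identical ref/alt residues, nonstandard
#' residues, or AF outside \[0, 1\] are errors.
#'
#' @param path TSV file.
#' @return `data.frame` with the input columns plus `maf`.
#' @export
read_missense_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant_id", "protein_id", "ref_aa", "alt_aa", "af")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missense table lacks column(s): ", paste(miss, collapse = ", "))
  validate_variants(df[, need], path)
}

#' Write a missense variant table
#'
#' @param variants Data frame as returned by [read_missense_table()].
#' @param path Output TSV.
#' @export
write_missense_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read missense variants from a VCF
#'
#' Consumes a VCF 4.x subset whose INFO field carries amino-acid annotation
#' in the keys `REF_AA` (Number=1), `ALT_AA` (Number=A) and `PROTEIN`
#' (Number=1), plus a per-ALT allele-frequency field named by `af_field`
#' (Number=A, e.g. `AFR_AF`). Multi-allelic records are split into one
#' variant per ALT allele with its own AF and ALT_AA. Records lacking the
#' amino-acid annotation, annotated as synonymous (ref residue equals alt
#' residue), or carrying a nonstandard residue are skipped with a logged
#' count. Annotation production (consequence calling) is out of scope: this
#' reader consumes annotation, it does not create it.
#'
#' @param path VCF file (plain or bgzipped).
#' @param af_field INFO key of the population allele frequency
#'   (default `"AFR_AF"`).
#' @return `data.frame` with columns `variant_id, protein_id, ref_aa,
#'   alt_aa, af, maf`.
#' @export
read_vcf_missense <- function(path, af_field = "AFR_AF") {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  hdr_info <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  if (!af_field %in% hdr_info)
    stop("VCF INFO lacks the allele-frequency field '", af_field, "'")
  evcf <- VariantAnnotation::expand(vcf)
  inf <- VariantAnnotation::info(evcf)
  af <- inf[[af_field]]
  ref_aa <- as.character(inf[["REF_AA"]])
  alt_aa <- as.character(inf[["ALT_AA"]])
  protein <- as.character(inf[["PROTEIN"]])
  n <- length(evcf)
  if (is.null(af)) stop("allele-frequency field '", af_field, "' unreadable")
  annotated <- !is.na(ref_aa) & !is.na(alt_aa) & !is.na(protein)
  standard <- annotated & ref_aa %in% AA20 & alt_aa %in% AA20
  missense <- standard & ref_aa != alt_aa
  n_skip <- sum(!missense)
  if (n_skip > 0)
    message(n_skip, " VCF record(s) skipped (unannotated, nonstandard residue, or not missense)")
  rr <- SummarizedExperiment::rowRanges(evcf)
  vid <- sprintf("%s:%d_%s/%s", as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr), as.character(rr$REF),
                 as.character(rr$ALT))
  df <- data.frame(variant_id = vid[missense], protein_id = protein[missense],
                   ref_aa = ref_aa[missense], alt_aa = alt_aa[missense],
                   af = as.numeric(af[missense]), stringsAsFactors = FALSE)
  validate_variants(df, path)
}

#' Stratify variants by minor allele frequency
#'
#' Splits variants into the rare stratum (MAF < 0.001, strict) and the three
#' nested cumulative common strata MAF > 0.001, > 0.01 and > 0.05 (strict
#' inequalities throughout). A variant with MAF exactly 0.001 falls in
#' neither the rare nor the > 0.001 stratum; such boundary variants are
#' returned separately and their count is logged.
#'
#' @param variants Data frame with a `maf` column.
#' @return Named list of data frames: `rare`, `gt_001`, `gt_01`, `gt_05`,
#'   `boundary`.
#' @export
stratify_by_maf <- function(variants) {
  stopifnot("maf" %in% names(variants))
  out <- list(rare = variants[variants$maf < 0.001, , drop = FALSE],
              gt_001 = variants[variants$maf > 0.001, , drop = FALSE],
              gt_01 = variants[variants$maf > 0.01, , drop = FALSE],
              gt_05 = variants[variants$maf > 0.05, , drop = FALSE],
              boundary = variants[variants$maf == 0.001, , drop = FALSE])
  if (nrow(out$boundary) > 0)
    message(nrow(out$boundary),
            " variant(s) with MAF exactly 0.001 fall in no stratum")
  out
}

#' Conservative-fraction report for slow vs fast missense variants
#'
#' For each protein set (slow, fast), MAF stratum (all, rare, > 0.001,
#' > 0.01, > 0.05) and scoring matrix, computes the conservative fraction of
#' the variant amino-acid changes. An empty stratum yields an undefined
#' (NA-fraction) cell rather than an error.
#'
#' @param slow,fast Non-empty missense variant data frames (with `maf`).
#' @param matrices Named list of `aa_subst_matrix` (default all four).
#' @return `data.frame` with columns `set`, `stratum`, `matrix`,
#'   `n_conservative`, `n_total`, `fraction`.
#' @export
snp_fraction_report <- function(slow, fast, matrices = conservation_matrices()) {
  if (nrow(slow) == 0L || nrow(fast) == 0L)
    stop("both the slow and the fast variant sets must be non-empty")
  sets <- list(slow = slow, fast = fast)
  rows <- list()
  for (sn in names(sets)) {
    strata <- c(list(all = sets[[sn]]),
                stratify_by_maf(sets[[sn]])[c("rare", "gt_001", "gt_01", "gt_05")])
    for (st in names(strata)) for (mn in names(matrices)) {
      cf <- conservative_fraction(strata[[st]], matrices[[mn]])
      rows[[length(rows) + 1L]] <-
        data.frame(set = sn, stratum = st, matrix = mn,
                   n_conservative = cf$n_conservative, n_total = cf$n_total,
                   fraction = cf$fraction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
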