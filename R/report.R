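# Pipeline orchestration: run the fixed-substitution and SNP analyses end
# to end and emit the rate-bin table, the bin-wise and stratum-wise fraction
# reports with chi-squared annotations, and a run manifest carrying a
# configuration hash. Outputs are deterministic given inputs and config.

#' Hash a run configuration
#'
#' MD5 of the deparsed configuration list; identical configs always share a
#' hash and differing configs practically never do.
#'
#' @param config A list.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, output_dir, stage) {
  lines <- c(sprintf("stage\t%s", stage),
             sprintf("package_version\t%s", as.character(utils::packageVersion("aacons"))),
             sprintf("config_hash\t%s", config_hash(config)),
             vapply(sort(names(config)), function(k)
               sprintf("config.%s\t%s", k,
                       paste(deparse(config[[k]]), collapse = " ")), ""))
  writeLines(lines, file.path(output_dir, paste0(stage, "_manifest.tsv")))
}

aln_with_stats <- function(alignments) {
  stats <- do.call(rbind, lapply(alignments, alignment_stats))
  list(alignments = alignments, stats = stats)
}

#' Run the fixed-substitution (ortholog) analysis
#'
#' Computes alignment statistics, drops ineligible proteins (length <= 200
#' or identity <= 60), classifies the rest into rate bins, pools
#' substitutions per bin and writes: the rate-bin fraction table
#' (`fixed_fraction_table.tsv`, one row per populated stratum/bin cell with
#' all four matrix fractions, protein counts and mean lengths), the bin-wise
#' comparison report (`fixed_bin_comparisons.tsv`, chi-squared of each bin
#' against the next-faster bin in the same stratum panel, with significance
#' tiers), and a manifest with the config hash.
#'
#' @param alignments List of `pairwise_aln` (e.g. from [global_align()] or
#'   [read_alignment_table()]`$alignments`).
#' @param output_dir Output directory (created if needed).
#' @param matrices Named list of `aa_subst_matrix`.
#' @param per_protein Average per-protein fractions instead of pooling.
#' @return Invisibly, a list with `classified`, `fraction_table`,
#'   `comparisons` and output paths.
#' @export
run_fixed_analysis <- function(alignments, output_dir,
                               matrices = conservation_matrices(),
                               per_protein = FALSE) {
  if (!length(alignments)) stop("no input alignments")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- aln_with_stats(alignments)
  elig <- eligibility(dat$stats)
  if (!any(elig)) stop("no eligible proteins (need length > 200 and identity > 60)")
  stats <- dat$stats[elig, , drop = FALSE]
  alns <- dat$alignments[elig]
  classified <- classify_rate(stats)
  subs <- lapply(alns, extract_substitutions)
  tab <- group_fraction_table(classified, subs, matrices, per_protein = per_protein)
  comparisons <- bin_comparisons(tab, matrices)
  config <- list(analysis = "fixed", n_input = length(alignments),
                 matrices = names(matrices), per_protein = per_protein)
  p1 <- file.path(output_dir, "fixed_fraction_table.tsv")
  p2 <- file.path(output_dir, "fixed_bin_comparisons.tsv")
  write_fraction_table(tab, p1)
  write.table(comparisons, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write_classification(classified, file.path(output_dir, "classification.tsv"))
  write_manifest(config, output_dir, "fixed")
  invisible(list(classified = classified, fraction_table = tab,
                 comparisons = comparisons, paths = c(p1, p2)))
}

# chi-squared of each identity bin against the next (faster) bin within the
# same (length, gap) panel, per matrix
bin_comparisons <- function(tab, matrices) {
  rows <- list()
  for (ls in unique(tab$length_stratum)) for (gs in unique(tab$gap_stratum)) {
    panel <- tab[tab$length_stratum == ls & tab$gap_stratum == gs &
                   tab$identity_bin != OUT_OF_RANGE, , drop = FALSE]
    if (nrow(panel) < 2L) next
    for (i in seq_len(nrow(panel) - 1L)) for (mn in names(matrices)) {
      k1 <- panel[[paste0(mn, "_n_conservative")]][i]
      n1 <- panel[[paste0(mn, "_n_total")]][i]
      k2 <- panel[[paste0(mn, "_n_conservative")]][i + 1L]
      n2 <- panel[[paste0(mn, "_n_total")]][i + 1L]
      if (n1 == 0 || n2 == 0) next
      ct <- tryCatch(chi2_2x2(k1, n1 - k1, k2, n2 - k2), error = function(e) NULL)
      if (is.null(ct)) next
      rows[[length(rows) + 1L]] <- data.frame(
        length_stratum = ls, gap_stratum = gs, matrix = mn,
        bin = panel$identity_bin[i], vs_bin = panel$identity_bin[i + 1L],
        fraction = k1 / n1, vs_fraction = k2 / n2,
        statistic = ct$statistic, p_value = ct$p_value,
        tier = significance_tier(ct$p_value), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Run the missense-SNP (standing variation) analysis
#'
#' Partitions variants into the slow and fast protein sets by id membership,
#' then writes: per-set per-matrix score histograms
#' (`snp_score_histograms.tsv`), the stratified conservative-fraction report
#' (`snp_fraction_report.tsv`) with two chi-squared annotations per cell --
#' slow vs fast within the same stratum, and stratum vs the rare stratum
#' within the same set -- and a manifest. Boundary variants (MAF exactly
#' 0.001) are counted in the manifest and fall in no stratum.
#'
#' @param variants Missense variant data frame (see
#'   [read_missense_table()]).
#' @param slow_proteins Character vector of protein ids forming the slowly
#'   evolving set; all other proteins are the fast set.
#' @param output_dir Output directory.
#' @param matrices Named list of `aa_subst_matrix`.
#' @return Invisibly, a list with `report`, `histograms` and output paths.
#' @export
run_snp_analysis <- function(variants, slow_proteins, output_dir,
                             matrices = conservation_matrices()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  slow <- variants[variants$protein_id %in% slow_proteins, , drop = FALSE]
  fast <- variants[!variants$protein_id %in% slow_proteins, , drop = FALSE]
  if (nrow(slow) == 0L) stop("slow variant set is empty")
  if (nrow(fast) == 0L) stop("fast variant set is empty")
  report <- snp_fraction_report(slow, fast, matrices)
  report <- annotate_snp_report(report)
  hists <- list()
  for (sn in c("slow", "fast")) for (mn in names(matrices)) {
    h <- score_histogram(if (sn == "slow") slow else fast, matrices[[mn]])
    if (nrow(h)) hists[[length(hists) + 1L]] <-
        cbind(data.frame(set = sn, matrix = mn, stringsAsFactors = FALSE), h)
  }
  hists <- do.call(rbind, hists)
  config <- list(analysis = "snp", n_variants = nrow(variants),
                 n_slow_proteins = length(slow_proteins),
                 matrices = names(matrices),
                 n_boundary_maf = sum(variants$maf == 0.001))
  p1 <- file.path(output_dir, "snp_fraction_report.tsv")
  p2 <- file.path(output_dir, "snp_score_histograms.tsv")
  write.table(report, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hists, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, output_dir, "snp")
  invisible(list(report = report, histograms = hists, paths = c(p1, p2)))
}

annotate_snp_report <- function(report) {
  report$p_vs_other_set <- NA_real_
  report$p_vs_rare <- NA_real_
  frac_res <- function(row) new_fraction_result(row$n_conservative, row$n_total)
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    other <- report[report$set != r$set & report$stratum == r$stratum &
                      report$matrix == r$matrix, ]
    if (nrow(other) == 1L && r$n_total > 0 && other$n_total > 0)
      report$p_vs_other_set[i] <- tryCatch(
        compare_fractions(frac_res(r), frac_res(other))$p_value,
        error = function(e) NA_real_)
    if (!r$stratum %in% c("all", "rare")) {
      rare <- report[report$set == r$set & report$stratum == "rare" &
                       report$matrix == r$matrix, ]
      if (nrow(rare) == 1L && r$n_total > 0 && rare$n_total > 0)
        report$p_vs_rare[i] <- tryCatch(
          compare_fractions(frac_res(r), frac_res(rare))$p_value,
          error = function(e) NA_real_)
    }
  }
  report$tier_vs_other_set <- ifelse(is.na(report$p_vs_other_set), "",
                                     significance_tier(report$p_vs_other_set))
  report$tier_vs_rare <- ifelse(is.na(report$p_vs_rare), "",
                                significance_tier(report$p_vs_rare))
  report
}
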