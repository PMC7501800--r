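# Small in-code fixtures shared by the tests.

# a pairwise alignment from two already-aligned gapped strings
make_aln <- function(qseq, sseq, query_id = "q", hit_id = "h", score = NA_real_) {
  aacons:::new_pairwise_aln(query_id, hit_id, qseq, sseq, score)
}

# alignment-stats rows without running the aligner
make_stats <- function(query_length, percent_identity, n_gap_columns = 0,
                       query_id = "q", hit_id = "h") {
  data.frame(query_id = query_id, hit_id = hit_id,
             query_length = query_length, span = query_length + n_gap_columns,
             n_match = NA_integer_, n_mismatch = NA_integer_,
             n_gap_columns = n_gap_columns,
             percent_identity = percent_identity, stringsAsFactors = FALSE)
}

# write a normalized-matrix TSV for load_matrix tests
write_matrix_tsv <- function(values, path = tempfile(fileext = ".tsv")) {
  ab <- rownames(values)
  lines <- c(paste(c("", ab), collapse = "\t"),
             vapply(seq_along(ab), function(i)
               paste(c(ab[i], values[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

identity_norm_values <- function() {
  v <- diag(20)
  dimnames(v) <- list(AA20, AA20)
  v
}

write_mini_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           af_field = "AFR_AF") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Alt allele frequency\">", af_field),
    "##INFO=<ID=REF_AA,Number=1,Type=String,Description=\"Reference amino acid\">",
    "##INFO=<ID=ALT_AA,Number=A,Type=String,Description=\"Alternate amino acid\">",
    "##INFO=<ID=PROTEIN,Number=1,Type=String,Description=\"Protein id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records), path)
  path
}

make_variants <- function(ref_aa, alt_aa, af, protein_id = "P1") {
  n <- length(ref_aa)
  data.frame(variant_id = sprintf("v%03d", seq_len(n)),
             protein_id = rep_len(protein_id, n),
             ref_aa = ref_aa, alt_aa = alt_aa, af = af,
             maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
}
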