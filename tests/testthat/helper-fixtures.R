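# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from static data files.

# A single-row record builder with sane defaults: clean somatic site with
# bi-allelic tumor DNA and balanced RNA.
rec <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "C",
                nd_ref = 40L, nd_var = 0L, nr_ref = 30L, nr_var = 0L,
                td_ref = 30L, td_var = 10L, tr_ref = 22L, tr_var = 8L,
                sample_id = "S1") {
  variant_records(chrom, pos, ref, alt, nd_ref, nd_var, nr_ref, nr_var,
                  td_ref, td_var, tr_ref, tr_var, sample_id)
}

bind_records <- function(...) {
  validate_records <- getFromNamespace("validate_records", "somase")
  validate_records(do.call(rbind, lapply(list(...), as.data.frame)))
}

write_counts_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Annotation table row(s) matching read_annotations' layout.
write_annotations_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

annotation_row <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "C",
                           gene = "GENE0001", func_class = "missense",
                           cadd = 12.5, fathmm_score = -1.2,
                           fathmm_call = "pathogenic", gerp = 3.1,
                           polyphen = 0.9, grantham = 100, phast = 0.8,
                           in_cancer_gene_list = FALSE,
                           molecular_mode = "dominant") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             func_class = func_class, cadd = cadd, fathmm_score = fathmm_score,
             fathmm_call = fathmm_call, gerp = gerp, polyphen = polyphen,
             grantham = grantham, phast = phast,
             in_cancer_gene_list = in_cancer_gene_list,
             molecular_mode = molecular_mode, stringsAsFactors = FALSE)
}

# Reconstruct a cohort call table realising a given recurrence spectrum:
# `histogram` maps multiplicity -> number of unique mutations.
spectrum_calls <- function(histogram) {
  rows <- list()
  mut <- 0L
  for (m in as.integer(names(histogram))) {
    for (j in seq_len(histogram[[as.character(m)]])) {
      mut <- mut + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%03d", seq_len(m)),
        chrom = "chr1", pos = mut, ref = "A", alt = "C",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# The printed cohort recurrence spectrum: 1139 unique mutations of which
# 44 were seen in 2 samples, 12 in 3, 4 in 4, 2 in 5, and one each in 6
# and 7; the remaining 1075 are singletons.
PRINTED_SPECTRUM <- list("1" = 1075L, "2" = 44L, "3" = 12L, "4" = 4L,
                         "5" = 2L, "6" = 1L, "7" = 1L)

# Brute-force two-sided exact binomial oracle (independent of the
# implementation: explicit pmf, minimum-likelihood rule).
oracle_binom_two_sided <- function(k, n, p) {
  d <- vapply(0:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1))
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
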