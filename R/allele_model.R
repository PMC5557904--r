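#' Variant allele fraction
#'
#' Computes the variant allele fraction VAF = n(var) / (n(ref) + n(var)) from
#' reference- and variant-supporting read counts at a site. VAF is computed
#' separately for every dataset of a matched quartet (normal/tumor x DNA/RNA).
#'
#' @param ref_reads Non-negative integer vector of reference-supporting reads.
#' @param var_reads Non-negative integer vector of variant-supporting reads,
#'   recycled against `ref_reads`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' vaf(5, 5)    # 0.5
#' vaf(30, 10)  # 0.25
#' @export
vaf <- function(ref_reads, var_reads) {
  if (any(ref_reads < 0) || any(var_reads < 0))
    abort_value("read counts must be non-negative")
  depth <- ref_reads + var_reads
  if (any(depth < 1))
    abort_value("VAF undefined at zero depth; coverage-filter sites first")
  var_reads / depth
}

#' RNA:DNA allelic expression ratio
#'
#' The ratio V_RD = VAF(tumor RNA) / VAF(tumor DNA). Values near 1 mean the
#' transcriptome mirrors the genomic allele composition; values above 1
#' indicate over-representation of the variant allele in RNA, below 1
#' under-representation. Because it conditions on the tumor-DNA VAF, V_RD
#' absorbs sample-level composition effects such as tumor purity.
#'
#' The ratio is only meaningful at sites with a bi-allelic tumor-DNA signal,
#' so `vaf_tdna` must lie strictly inside (0, 1); the upstream somatic filter
#' enforces this. The ratio is not capped above 1.
#'
#' @param vaf_trna Tumor-RNA VAF, in `[0, 1]`.
#' @param vaf_tdna Tumor-DNA VAF, strictly inside `(0, 1)`.
#' @return Non-negative numeric vector.
#' @examples
#' v_rd(0.9, 0.3)  # 3: variant allele over-expressed
#' @export
v_rd <- function(vaf_trna, vaf_tdna) {
  if (any(vaf_trna < 0 | vaf_trna > 1))
    abort_precondition("vaf_trna must lie in [0, 1]")
  if (any(vaf_tdna <= 0 | vaf_tdna >= 1))
    abort_precondition("vaf_tdna must lie strictly in (0, 1) (bi-allelic tumor DNA)")
  vaf_trna / vaf_tdna
}

# Column layout of the canonical variant-record table. One row is one
# (sample, site) observation carrying the four matched count pairs.
QUAD_COUNT_COLS <- c(
  "nd_ref", "nd_var", "nr_ref", "nr_var",
  "td_ref", "td_var", "tr_ref", "tr_var"
)
RECORD_KEY_COLS <- c("sample_id", "chrom", "pos", "ref", "alt")
RECORD_COLS <- c("chrom", "pos", "ref", "alt", QUAD_COUNT_COLS, "sample_id")

#' Construct a variant-record table
#'
#' Builds the canonical data frame of per-(sample, site) matched read counts
#' used throughout the pipeline: one row per observation, with variant /
#' reference counts for normal DNA (`nd_*`), normal RNA (`nr_*`), tumor DNA
#' (`td_*`) and tumor RNA (`tr_*`). Input validation matches the TSV reader:
#' single-base substitutions only, non-negative integer counts, no duplicated
#' (sample, site) keys.
#'
#' @param chrom,pos,ref,alt Site key vectors: chromosome name, 1-based
#'   position, reference and alternate base (single base, `ref != alt`).
#' @param nd_ref,nd_var,nr_ref,nr_var,td_ref,td_var,tr_ref,tr_var
#'   Reference/variant read counts in the four datasets.
#' @param sample_id Sample identifier.
#' @return A `data.frame` with class `somase_records`.
#' @export
variant_records <- function(chrom, pos, ref, alt,
                            nd_ref, nd_var, nr_ref, nr_var,
                            td_ref, td_var, tr_ref, tr_var,
                            sample_id) {
  df <- data.frame(
    chrom = as.character(chrom), pos = pos, ref = as.character(ref),
    alt = as.character(alt),
    nd_ref = nd_ref, nd_var = nd_var, nr_ref = nr_ref, nr_var = nr_var,
    td_ref = td_ref, td_var = td_var, tr_ref = tr_ref, tr_var = tr_var,
    sample_id = as.character(sample_id),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

validate_records <- function(df, line_offset = 1L) {
  line_of <- function(i) i + line_offset  # physical line number incl. header
  if (nrow(df)) {
    if (any(!nzchar(df$chrom))) abort_value("chrom must be non-empty")
    if (any(!nzchar(df$sample_id))) abort_value("sample_id must be non-empty")
    bases <- c("A", "C", "G", "T")
    bad <- which(!(df$ref %in% bases) | !(df$alt %in% bases))
    if (length(bad))
      abort_value(sprintf(
        "only single-base A/C/G/T substitutions are supported (line %d: ref='%s' alt='%s')",
        line_of(bad[1]), df$ref[bad[1]], df$alt[bad[1]]))
    bad <- which(df$ref == df$alt)
    if (length(bad))
      abort_value(sprintf("ref and alt alleles identical at line %d", line_of(bad[1])))
    for (col in c("pos", QUAD_COUNT_COLS)) {
      v <- df[[col]]
      if (!is.numeric(v) || anyNA(v) || any(v != floor(v)))
        abort_value(sprintf(
          "column %s must contain integers (line %d)", col,
          line_of(which(!is.finite(v) | v != floor(v))[1] %||% 1L)))
      lo <- if (col == "pos") 1 else 0
      bad <- which(v < lo)
      if (length(bad))
        abort_value(sprintf("column %s has value %s below %d at line %d",
                            col, format(v[bad[1]]), lo, line_of(bad[1])))
      df[[col]] <- as.integer(v)
    }
    key <- do.call(paste, c(df[RECORD_KEY_COLS], sep = "\r"))
    if (anyDuplicated(key))
      abort_duplicate(sprintf(
        "duplicated (sample, site) record at line %d: %s %s:%d",
        line_of(which(duplicated(key))[1]),
        df$sample_id[which(duplicated(key))[1]],
        df$chrom[which(duplicated(key))[1]],
        df$pos[which(duplicated(key))[1]]))
  }
  class(df) <- c("somase_records", "data.frame")
  df
}

record_depths <- function(records, dataset = c("td", "tr", "nd", "nr")) {
  dataset <- match.arg(dataset)
  records[[paste0(dataset, "_ref")]] + records[[paste0(dataset, "_var")]]
}

record_vaf <- function(records, dataset = c("td", "tr", "nd", "nr")) {
  dataset <- match.arg(dataset)
  vaf(records[[paste0(dataset, "_ref")]], records[[paste0(dataset, "_var")]])
}

site_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
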