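#' Read a matched four-way read-count table
#'
#' Reads per-site variant/reference read counts for the four matched datasets
#' (normal exome `nd`, normal transcriptome `nr`, tumor exome `td`, tumor
#' transcriptome `tr`) of every sample.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{Tab-delimited with header columns `chrom, pos, ref, alt,
#'     nd_ref, nd_var, nr_ref, nr_var, td_ref, td_var, tr_ref, tr_var,
#'     sample_id`. Row order is preserved.}
#'   \item{`vcf_ad`}{A VCF 4.x file whose genotype field carries `AD`
#'     (ref,alt allelic depths) for four named samples; `vcf_samples` maps the
#'     VCF sample columns to the four roles and `sample_id` names the patient.
#'     Requires the VariantAnnotation package.}
#' }
#'
#' Only single-nucleotide substitutions are accepted; indel rows raise a value
#' error (the analysis is defined for somatic point mutations).
#'
#' @param path Input file path.
#' @param dialect `"tsv"` (default) or `"vcf_ad"`.
#' @param vcf_samples Named character vector mapping roles
#'   `c(normal_dna=, normal_rna=, tumor_dna=, tumor_rna=)` to VCF sample
#'   columns (vcf_ad dialect only).
#' @param sample_id Patient identifier for vcf_ad records.
#' @return A `somase_records` data frame (see [variant_records()]).
#' @export
read_quad_counts <- function(path, dialect = c("tsv", "vcf_ad"),
                             vcf_samples = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (dialect == "tsv") read_quad_counts_tsv(path) else
    read_quad_counts_vcf(path, vcf_samples, sample_id)
}

read_quad_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLS, names(df))
  if (length(missing))
    abort_format(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  df <- df[RECORD_COLS]
  for (col in c("pos", QUAD_COUNT_COLS)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      abort_value(sprintf("column %s is not numeric at line %d", col, bad[1] + 1L))
    df[[col]] <- v
  }
  validate_records(df, line_offset = 1L)
}

read_quad_counts_vcf <- function(path, vcf_samples, sample_id) {
  roles <- c("normal_dna", "normal_rna", "tumor_dna", "tumor_rna")
  if (is.null(vcf_samples) || !all(roles %in% names(vcf_samples)))
    abort_usage("vcf_ad dialect needs vcf_samples naming normal_dna, normal_rna, tumor_dna, tumor_rna")
  if (is.null(sample_id)) abort_usage("vcf_ad dialect needs a sample_id")
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort_usage("the vcf_ad dialect requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  present <- colnames(vcf)
  absent <- setdiff(unname(vcf_samples[roles]), present)
  if (length(absent))
    abort_format(sprintf("VCF lacks sample column(s): %s", paste(absent, collapse = ", ")))
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) abort_format("VCF has no AD genotype field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  if (any(lengths(altl) != 1L))
    abort_value("multi-allelic VCF rows are not supported; split them first")
  alt <- as.character(unlist(altl))
  counts <- lapply(roles, function(role) {
    col <- vcf_samples[[role]]
    m <- do.call(rbind, ad[, col])
    if (is.null(dim(m)) || ncol(m) < 2) abort_format("AD field must hold ref,alt depth pairs")
    m[, 1:2, drop = FALSE]
  })
  names(counts) <- roles
  variant_records(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref, alt = alt,
    nd_ref = counts$normal_dna[, 1], nd_var = counts$normal_dna[, 2],
    nr_ref = counts$normal_rna[, 1], nr_var = counts$normal_rna[, 2],
    td_ref = counts$tumor_dna[, 1], td_var = counts$tumor_dna[, 2],
    tr_ref = counts$tumor_rna[, 1], tr_var = counts$tumor_rna[, 2],
    sample_id = sample_id
  )
}

#' Read genomic exclusion intervals (BED or SEG)
#'
#' Intervals mark regions whose variants must be excluded from allelic
#' analysis: known imprinted regions (BED) and per-sample copy-number
#' segments (SEG). All intervals are converted at this boundary to the
#' internal 1-based inclusive convention (`bed_start + 1 .. bed_end`).
#'
#' @param path Input file path.
#' @param dialect `"bed"` (0-based half-open, 3+ columns, optional 4th name
#'   column) or `"seg"` (tab-delimited segmentation: `sample, chrom, start,
#'   end[, num_mark], seg_mean`; 1-based inclusive as emitted by DNAcopy-style
#'   tools).
#' @param label Provenance label stored on each interval. Defaults to
#'   `"imprinted"` for BED and `"CNA"` for SEG; the CNA label is what the
#'   copy-number filter keys on.
#' @return A data frame with columns `chrom, start, end, label, value,
#'   sample` (1-based inclusive; `value` holds the SEG mean, `sample` is `NA`
#'   for cohort-wide intervals such as imprinted regions).
#' @export
read_intervals <- function(path, dialect = c("bed", "seg"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (dialect == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3) abort_format("BED needs at least 3 columns")
    out <- data.frame(
      chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]) + 1L,  # 0-based half-open -> 1-based inclusive
      end = as.integer(df[[3]]),
      label = if (!is.null(label)) label else
        if (ncol(df) >= 4) as.character(df[[4]]) else "imprinted",
      value = NA_real_, sample = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("sample", "chrom", "start", "end", "seg_mean")
    missing <- setdiff(need, names(df))
    if (length(missing))
      abort_format(sprintf("SEG missing column(s): %s", paste(missing, collapse = ", ")))
    out <- data.frame(
      chrom = as.character(df$chrom),
      start = as.integer(df$start), end = as.integer(df$end),
      label = label %||% "CNA",
      value = as.numeric(df$seg_mean),
      sample = as.character(df$sample),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(out$start > out$end | out$start < 1L)
  if (length(bad))
    abort_value(sprintf("invalid interval at line %d: start %d end %d",
                        bad[1], out$start[bad[1]], out$end[bad[1]]))
  class(out) <- c("somase_intervals", "data.frame")
  out
}

ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "func_class",
                     "cadd", "fathmm_score", "fathmm_call", "gerp", "polyphen",
                     "grantham", "phast", "in_cancer_gene_list", "molecular_mode")
FUNC_CLASSES <- c("missense", "non-coding", "stop", "synonymous")
SCORE_COLS <- c("cadd", "fathmm_score", "gerp", "polyphen", "grantham", "phast")

#' Read a per-variant annotation table
#'
#' Tab-delimited annotation keyed by (chrom, pos, ref, alt): gene symbol,
#' functional class, pathogenicity (CADD, FATHMM, PolyPhen) and conservation
#' (GERP, PhastCons, Grantham) scores, cancer-gene-list membership and
#' molecular mode. Empty score cells become `NA` — explicitly absent, never
#' zero — and downstream correlations drop them pairwise.
#'
#' @param path Input file path.
#' @return A data frame keyed by (chrom, pos, ref, alt).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing))
    abort_format(sprintf("annotation table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  df <- df[ANNOTATION_COLS]
  bad <- which(!(df$func_class %in% FUNC_CLASSES))
  if (length(bad))
    abort_value(sprintf(
      "func_class '%s' at line %d outside vocabulary {%s}",
      df$func_class[bad[1]], bad[1] + 1L, paste(FUNC_CLASSES, collapse = ", ")))
  ok_call <- is.na(df$fathmm_call) | df$fathmm_call %in% c("pathogenic", "neutral")
  if (!all(ok_call))
    abort_value(sprintf("fathmm_call must be pathogenic/neutral (line %d)",
                        which(!ok_call)[1] + 1L))
  ok_mode <- is.na(df$molecular_mode) | df$molecular_mode %in% c("dominant", "recessive")
  if (!all(ok_mode))
    abort_value(sprintf("molecular_mode must be dominant/recessive (line %d)",
                        which(!ok_mode)[1] + 1L))
  for (col in SCORE_COLS) df[[col]] <- as.numeric(df[[col]])
  df$pos <- as.integer(df$pos)
  df$in_cancer_gene_list <- as.logical(df$in_cancer_gene_list)
  df
}

CALL_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf_tdna",
               "vaf_trna", "v_rd", "p_value", "q_value", "call")
CALL_LEVELS <- c("SOM_E", "SOM_L", "EXPRESSED_BALANCED")

#' Write / read per-site expression calls
#'
#' Calls are emitted as a tab-delimited table with columns `sample_id, chrom,
#' pos, ref, alt, vaf_tdna, vaf_trna, v_rd, p_value, q_value, call`. Real
#' values are written with 15 significant digits so a write/read cycle
#' round-trips to at least 12 significant digits; integer fields round-trip
#' bit-exactly.
#'
#' @param calls A data frame of expression calls (see
#'   [call_expression_status()]).
#' @param path Output (input) file path.
#' @return `write_calls` returns `path` invisibly; `read_calls` returns the
#'   calls data frame.
#' @export
write_calls <- function(calls, path) {
  missing <- setdiff(CALL_COLS, names(calls))
  if (length(missing))
    abort_value(sprintf("calls missing column(s): %s", paste(missing, collapse = ", ")))
  if (!dir.exists(dirname(path)))
    abort_io(sprintf("cannot write calls: directory does not exist: %s", dirname(path)))
  out <- calls[CALL_COLS]
  for (col in c("vaf_tdna", "vaf_trna", "v_rd", "p_value", "q_value"))
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write calls to %s", path))
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  missing <- setdiff(CALL_COLS, names(df))
  if (length(missing))
    abort_format(sprintf("calls file missing column(s): %s",
                         paste(missing, collapse = ", ")))
  bad <- which(!(df$call %in% CALL_LEVELS))
  if (length(bad))
    abort_value(sprintf("unknown call '%s' at line %d", df$call[bad[1]], bad[1] + 1L))
  class(df) <- c("expression_calls", "data.frame")
  df
}
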