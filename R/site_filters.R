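#' Site-filter configuration
#'
#' Thresholds governing which (sample, site) pairs enter the allelic
#' analysis. Defaults follow the exclusion rules the pipeline is built
#' around:
#' \itemize{
#'   \item `min_depth = 10`: sites covered by fewer than 10 reads in the
#'     tumor DNA or tumor RNA are dropped; exactly 10 reads passes (the rule
#'     excludes strictly "less than 10").
#'   \item `germline_max_var_reads = 1`: a site is "present in the normal
#'     DNA or RNA" — hence of suspected germline origin — when either normal
#'     dataset shows more variant reads than this; one stray read is
#'     tolerated as sequencing error.
#'   \item `germline_error_rate = 0.001`: nominal per-base sequencing error,
#'     recorded in the manifest and used by the simulator; reserved for a
#'     future binomial germline test.
#'   \item `cna_abs_segmean_threshold = 0.1`: a copy-number segment counts as
#'     "affected" when `|seg_mean|` exceeds this; near-zero segments are
#'     copy-neutral and do not exclude sites.
#'   \item `hypermutator_sd_multiplier = 3`: samples whose somatic mutation
#'     count exceeds the cohort mean by more than this many sample standard
#'     deviations (n-1 denominator) are excluded.
#' }
#'
#' @param min_depth,germline_max_var_reads,germline_error_rate,cna_abs_segmean_threshold,hypermutator_sd_multiplier
#'   See above.
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L,
                          germline_max_var_reads = 1L,
                          germline_error_rate = 0.001,
                          cna_abs_segmean_threshold = 0.1,
                          hypermutator_sd_multiplier = 3.0) {
  if (min_depth < 1) abort_config("min_depth must be >= 1")
  if (germline_max_var_reads < 0 || germline_error_rate < 0 ||
      cna_abs_segmean_threshold < 0 || hypermutator_sd_multiplier < 0)
    abort_config("filter thresholds must be non-negative")
  structure(list(
    min_depth = as.integer(min_depth),
    germline_max_var_reads = as.integer(germline_max_var_reads),
    germline_error_rate = germline_error_rate,
    cna_abs_segmean_threshold = cna_abs_segmean_threshold,
    hypermutator_sd_multiplier = hypermutator_sd_multiplier
  ), class = "filter_config")
}

#' Coverage filter
#'
#' A record passes coverage when both the tumor-DNA and tumor-RNA depth
#' (ref + var reads) reach `config$min_depth`. Normal-tissue depth is not a
#' criterion here; the germline check handles the normal datasets.
#'
#' @param records A `somase_records` data frame.
#' @param config A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
passes_coverage <- function(records, config = filter_config()) {
  record_depths(records, "td") >= config$min_depth &
    record_depths(records, "tr") >= config$min_depth
}

#' Somatic bi-allelic filter
#'
#' TRUE when the variant looks somatic (at most `germline_max_var_reads`
#' variant reads in each of normal DNA and normal RNA) and the tumor DNA
#' carries a bi-allelic signal, `0 < VAF(tDNA) < 1`. The bi-allelic
#' requirement ensures later allelic imbalance in RNA is attributable to
#' expression, not to genomic loss of an allele.
#'
#' @inheritParams passes_coverage
#' @return Logical vector, one element per record.
#' @export
is_somatic_biallelic <- function(records, config = filter_config()) {
  td_depth <- record_depths(records, "td")
  tvaf <- ifelse(td_depth > 0, records$td_var / pmax(td_depth, 1L), NA_real_)
  records$nd_var <= config$germline_max_var_reads &
    records$nr_var <= config$germline_max_var_reads &
    !is.na(tvaf) & tvaf > 0 & tvaf < 1
}

#' Excluded-region overlap
#'
#' TRUE for sites falling inside an exclusion interval: any non-CNA interval
#' (e.g. imprinted regions), or a CNA segment whose `|seg_mean|` exceeds
#' `config$cna_abs_segmean_threshold`. Intervals carrying a `sample` value
#' only apply to records of that sample (CNA segments are per-sample);
#' intervals with `sample = NA` apply cohort-wide. Coordinates are 1-based
#' inclusive on both sides.
#'
#' @param records A `somase_records` data frame (columns `chrom`, `pos`,
#'   `sample_id`).
#' @param intervals Interval data frame from [read_intervals()].
#' @param config A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
overlaps_excluded_region <- function(records, intervals, config = filter_config()) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, nrow(records)))
  active <- intervals$label != "CNA" |
    (!is.na(intervals$value) & abs(intervals$value) > config$cna_abs_segmean_threshold)
  intervals <- intervals[active, , drop = FALSE]
  if (!nrow(intervals)) return(rep(FALSE, nrow(records)))
  vapply(seq_len(nrow(records)), function(i) {
    hit <- intervals$chrom == records$chrom[i] &
      intervals$start <= records$pos[i] & records$pos[i] <= intervals$end &
      (is.na(intervals$sample) | intervals$sample == records$sample_id[i])
    any(hit)
  }, logical(1))
}

#' Hypermutator exclusion
#'
#' Flags samples carrying an extreme somatic mutation burden: count greater
#' than the cohort mean plus `hypermutator_sd_multiplier` sample standard
#' deviations (n-1 denominator), typically caused by clustered genomic
#' rearrangements.
#'
#' @param per_sample_counts Named numeric vector: somatic mutation count per
#'   sample (names are sample ids). At least two samples required.
#' @param config A [filter_config()].
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
exclude_hypermutators <- function(per_sample_counts, config = filter_config()) {
  if (length(per_sample_counts) < 2)
    abort_precondition("hypermutator exclusion needs at least 2 samples")
  mu <- mean(per_sample_counts)
  sdev <- stats::sd(per_sample_counts)
  cutoff <- mu + config$hypermutator_sd_multiplier * sdev
  names(per_sample_counts)[per_sample_counts > cutoff]
}

FILTER_REASONS <- c("low_coverage_dna", "low_coverage_rna", "imprinted",
                    "cna_overlap", "germline", "not_biallelic_tumor_dna")

#' Apply all site filters
#'
#' Runs the full exclusion ledger over a record table and returns the
#' retained records together with a per-record verdict. Filters are pure
#' predicates, so the retained set does not depend on application order. A
#' record is retained iff it accumulates no reason from:
#' `low_coverage_dna`, `low_coverage_rna`, `imprinted`, `cna_overlap`,
#' `germline`, `not_biallelic_tumor_dna`.
#'
#' @param records A `somase_records` data frame.
#' @param intervals Optional exclusion intervals ([read_intervals()]); rows
#'   labelled `"CNA"` are treated as copy-number segments, all other labels
#'   as unconditional exclusions (imprinted regions).
#' @param config A [filter_config()].
#' @return A list with `retained` (subset of `records`) and `verdicts`
#'   (data frame: record keys, `retained` flag, comma-separated `reasons`).
#' @export
apply_filters <- function(records, intervals = NULL, config = filter_config()) {
  n <- nrow(records)
  cov_dna <- record_depths(records, "td") >= config$min_depth
  cov_rna <- record_depths(records, "tr") >= config$min_depth
  germ <- records$nd_var > config$germline_max_var_reads |
    records$nr_var > config$germline_max_var_reads
  td_depth <- record_depths(records, "td")
  tvaf <- ifelse(td_depth > 0, records$td_var / pmax(td_depth, 1L), NA_real_)
  biall <- !is.na(tvaf) & tvaf > 0 & tvaf < 1
  imprinted <- cna <- rep(FALSE, n)
  if (!is.null(intervals) && nrow(intervals)) {
    imprinted <- overlaps_excluded_region(
      records, intervals[intervals$label != "CNA", , drop = FALSE], config)
    cna <- overlaps_excluded_region(
      records, intervals[intervals$label == "CNA", , drop = FALSE], config)
  }
  reasons <- vapply(seq_len(n), function(i) {
    r <- c(
      if (!cov_dna[i]) "low_coverage_dna",
      if (!cov_rna[i]) "low_coverage_rna",
      if (imprinted[i]) "imprinted",
      if (cna[i]) "cna_overlap",
      if (germ[i]) "germline",
      if (!biall[i]) "not_biallelic_tumor_dna"
    )
    paste(r, collapse = ",")
  }, character(1))
  retained <- !nzchar(reasons)
  verdicts <- data.frame(records[RECORD_KEY_COLS], retained = retained,
                         reasons = reasons, stringsAsFactors = FALSE)
  kept <- records[retained, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(records)
  list(retained = kept, verdicts = verdicts)
}
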