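#' Expression-call configuration
#'
#' Parameters of the binomial allelic-imbalance caller.
#'
#' @param alpha FDR significance level for the Benjamini-Hochberg-adjusted
#'   binomial test (default 0.05).
#' @param null_mode Null RNA variant fraction: `"dna_matched"` (default)
#'   tests the tumor-RNA counts against the site's own tumor-DNA VAF, so
#'   departures reflect expression rather than genome composition (purity,
#'   residual structure); `"half"` tests against 0.5.
#' @param tau_e Minimum tumor-RNA VAF for a SOM-E (over-expressed, variant
#'   allele essentially mono-allelic in RNA) call; default 0.9.
#' @param tau_l Maximum tumor-RNA VAF for a SOM-L (lost from the
#'   transcriptome) call; default 0.05.
#' @return A list with class `call_config`.
#' @details Significance alone does not determine a call: a site must be
#'   both FDR-significant (`q < alpha`) and beyond the hard VAF threshold
#'   (`tau_e` / `tau_l`), because "mono-allelic" is a statement about the
#'   fraction, not only about incompatibility with the null.
#' @export
call_config <- function(alpha = 0.05,
                        null_mode = c("dna_matched", "half"),
                        tau_e = 0.9, tau_l = 0.05) {
  null_mode <- match.arg(null_mode)
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must lie in (0, 1)")
  if (!(tau_l >= 0 && tau_l < tau_e && tau_e <= 1))
    abort_config("need 0 <= tau_l < tau_e <= 1")
  structure(list(alpha = alpha, null_mode = null_mode,
                 tau_e = tau_e, tau_l = tau_l, fdr_method = "BH"),
            class = "call_config")
}

# Relative tolerance for pmf ties in the two-sided exact test.
BINOM_TIE_RTOL <- 1e-7

#' Exact binomial test p-value
#'
#' Exact tail probability for `k` successes out of `n` trials under success
#' probability `p0`. The two-sided p-value uses the minimum-likelihood
#' convention: the sum of probabilities of all outcomes whose point
#' probability does not exceed that of the observed `k`, with a relative
#' tolerance of 1e-7 for floating-point ties.
#'
#' @param k Observed successes, `0 <= k <= n` (vectorised).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
exact_binomial_p <- function(k, n, p0,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(p0 <= 0 | p0 >= 1)) abort_precondition("p0 must lie strictly in (0, 1)")
  if (any(k < 0 | k > n)) abort_precondition("need 0 <= k <= n")
  m <- max(length(k), length(n), length(p0))
  k <- rep_len(k, m); n <- rep_len(n, m); p0 <- rep_len(p0, m)
  vapply(seq_len(m), function(i) {
    switch(alternative,
      greater = min(1, stats::pbinom(k[i] - 1L, n[i], p0[i], lower.tail = FALSE)),
      less = min(1, stats::pbinom(k[i], n[i], p0[i])),
      two_sided = {
        d <- stats::dbinom(0:n[i], n[i], p0[i])
        min(1, sum(d[d <= d[k[i] + 1L] * (1 + BINOM_TIE_RTOL)]))
      }
    )
  }, numeric(1))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH step-up adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, returned in the
#' original input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort_precondition("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p_values[o] * m / seq(m, 1L)))[ro]
}

#' Classify allelic expression status of retained somatic sites
#'
#' For each retained record the tumor-RNA variant reads are tested against a
#' binomial null with `p0` equal to the site's tumor-DNA VAF
#' (`null_mode = "dna_matched"`) or 0.5 (`"half"`), two-sided and exact.
#' P-values are adjusted jointly across the batch by Benjamini-Hochberg and
#' each site is called:
#' \itemize{
#'   \item `SOM_E` — `q < alpha` and `VAF(tRNA) >= tau_e` (variant allele
#'     over-expressed, essentially mono-allelic in RNA);
#'   \item `SOM_L` — `q < alpha` and `VAF(tRNA) <= tau_l` (variant allele
#'     lost from the transcriptome);
#'   \item `EXPRESSED_BALANCED` otherwise.
#' }
#'
#' @param records A `somase_records` data frame that already passed
#'   [apply_filters()] (tumor DNA bi-allelic, depths adequate).
#' @param config A [call_config()].
#' @return An `expression_calls` data frame: record keys, `vaf_tdna`,
#'   `vaf_trna`, `v_rd`, `p_value`, `q_value`, `call`.
#' @export
call_expression_status <- function(records, config = call_config()) {
  if (nrow(records) == 0L) {
    out <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      vaf_tdna = numeric(), vaf_trna = numeric(),
                      v_rd = numeric(), p_value = numeric(),
                      q_value = numeric(), call = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("expression_calls", "data.frame")
    return(out)
  }
  vaf_td <- record_vaf(records, "td")
  if (any(vaf_td <= 0 | vaf_td >= 1))
    abort_precondition("records must be bi-allelic in tumor DNA (0 < VAF < 1); run apply_filters first")
  vaf_tr <- record_vaf(records, "tr")
  p0 <- if (config$null_mode == "dna_matched") vaf_td else rep(0.5, nrow(records))
  p <- exact_binomial_p(records$tr_var, record_depths(records, "tr"), p0,
                        alternative = "two_sided")
  q <- bh_adjust(p)
  call <- ifelse(q < config$alpha & vaf_tr >= config$tau_e, "SOM_E",
          ifelse(q < config$alpha & vaf_tr <= config$tau_l, "SOM_L",
                 "EXPRESSED_BALANCED"))
  out <- data.frame(
    sample_id = records$sample_id, chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    vaf_tdna = vaf_td, vaf_trna = vaf_tr, v_rd = vaf_tr / vaf_td,
    p_value = p, q_value = q, call = call, stringsAsFactors = FALSE
  )
  class(out) <- c("expression_calls", "data.frame")
  out
}
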