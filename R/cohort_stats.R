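#' Mutation recurrence spectrum
#'
#' Counts, across samples, how many unique mutations — keyed by
#' (chrom, pos, ref, alt) — were observed in exactly m samples, and derives
#' the total occurrence count and the singleton fraction (mutations private
#' to a single sample).
#'
#' @param calls An `expression_calls` data frame (or any data frame with
#'   `sample_id, chrom, pos, ref, alt` columns) spanning the cohort.
#' @return A list of class `recurrence_spectrum`:
#'   `multiplicity_histogram` (named integer vector: multiplicity ->
#'   number of unique mutations), `unique_count`, `total_count`,
#'   `singleton_fraction`.
#' @export
recurrence_spectrum <- function(calls) {
  key <- site_key(calls)
  pair <- paste(calls$sample_id, key, sep = "\r")
  pair_key <- key[!duplicated(pair)]     # distinct (sample, site) occurrences
  mult <- table(pair_key)
  hist <- table(as.integer(mult))
  histogram <- as.integer(hist)
  names(histogram) <- names(hist)
  unique_count <- length(mult)
  total_count <- sum(as.integer(mult))
  singleton_fraction <- if (unique_count)
    sum(mult == 1L) / unique_count else NA_real_
  structure(list(
    multiplicity_histogram = histogram,
    unique_count = unique_count,
    total_count = total_count,
    singleton_fraction = singleton_fraction
  ), class = "recurrence_spectrum")
}

#' @export
print.recurrence_spectrum <- function(x, ...) {
  cat(sprintf("Recurrence spectrum: %d occurrences of %d unique mutations\n",
              x$total_count, x$unique_count))
  cat(sprintf("  singletons: %.1f%%\n", 100 * x$singleton_fraction))
  m <- x$multiplicity_histogram
  for (i in seq_along(m))
    cat(sprintf("  seen in %s sample(s): %d\n", names(m)[i], m[i]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; pairs where either value is
#' missing are dropped (annotation scores are absent at some sites and must
#' never be imputed as zero).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_precondition("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    abort_insufficient_data("need at least 3 complete pairs for a rank correlation")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) abort_insufficient_data("a variable is constant after removing missing pairs")
  num / den
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square approximation with k-1 degrees of freedom, or from a seeded
#' label-permutation null for very small groups.
#'
#' @param groups A list of numeric vectors, one per group (each non-empty,
#'   at least two groups, total n >= 3).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @param seed RNG seed for the permutation null.
#' @return A list: `statistic` (H, tie-corrected), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 2000L, seed = 1L) {
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2)
    abort_precondition("need at least two groups")
  if (any(!lengths(groups))) abort_precondition("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) abort_precondition("need total n >= 3")
  g <- rep(seq_along(groups), lengths(groups))
  H <- kw_statistic(x, g)
  k <- length(groups)
  p <- if (p_method == "chisq") {
    stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  } else {
    with_private_seed(seed, {
      perm <- vapply(seq_len(n_perm), function(i) kw_statistic(x, sample(g)),
                     numeric(1))
      (1 + sum(perm >= H - 1e-12)) / (n_perm + 1)
    })
  }
  list(statistic = H, df = k - 1, p_value = p)
}

kw_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

#' 2x2 contingency test
#'
#' Association p-value for a 2x2 count table by either the two-sided Fisher
#' exact test (full hypergeometric enumeration over tables with the observed
#' margins, minimum-likelihood two-sided rule) or a Pearson chi-square in
#' which Yates's continuity correction is applied automatically whenever any
#' cell holds fewer than 5 counts.
#'
#' @param table A 2x2 matrix of non-negative integer counts with at least
#'   one positive entry.
#' @param method `"fisher_exact"` (default) or `"chi2_yates_auto"`.
#' @return The p-value.
#' @export
contingency_2x2 <- function(table, method = c("fisher_exact", "chi2_yates_auto")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) abort_precondition("table must be 2x2")
  if (any(tab < 0) || any(tab != floor(tab)))
    abort_precondition("counts must be non-negative integers")
  n <- sum(tab)
  if (n == 0) abort_precondition("all-zero table")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (method == "fisher_exact") {
    lo <- max(0L, c1 - r2); hi <- min(r1, c1)
    if (lo == hi) return(1)
    support <- lo:hi
    probs <- stats::dhyper(support, c1, c2, r1)
    p_obs <- probs[match(a, support)]
    min(1, sum(probs[probs <= p_obs * (1 + BINOM_TIE_RTOL)]))
  } else {
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
      abort_precondition("chi-square undefined with a zero margin")
    yates <- any(tab < 5)
    num <- abs(a * d - b * c_)
    if (yates) num <- max(0, num - n / 2)
    chi2 <- n * num^2 / (r1 * r2 * c1 * c2)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
}

#' Stratified allelic-expression summary
#'
#' Splits calls by an annotation stratum (e.g. functional class, or cancer
#' gene list membership), summarising per group the V_RD distribution and
#' the SOM-E / SOM-L / balanced class counts, then tests:
#' \itemize{
#'   \item V_RD location across strata: Kruskal-Wallis by default; Welch
#'     t-tests pairwise when `location_test = "t"` (two strata at a time).
#'   \item Call-class proportions: for every pair of strata and each of
#'     SOM_E, SOM_L, a 2x2 contingency test (class vs rest x stratum).
#' }
#' All contingency p-values are BH-adjusted jointly.
#'
#' @param calls An `expression_calls` data frame.
#' @param annotations Annotation data frame from [read_annotations()];
#'   joined to the calls by (chrom, pos, ref, alt). May be omitted when
#'   `calls` already carries the stratum column.
#' @param stratum Name of the grouping column (e.g. `"func_class"`,
#'   `"in_cancer_gene_list"`, `"fathmm_call"`).
#' @param location_test `"kruskal"` (default) or `"t"`.
#' @param contingency_method Passed to [contingency_2x2()].
#' @return A list of class `stratified_summary`: `stratum`, `groups` (named
#'   list of V_RD vectors), `class_counts` (strata x call classes),
#'   `location` (test result or NULL for a single stratum),
#'   `contingency` (data frame of pairwise tests with q-values, or NULL).
#' @export
stratified_summary <- function(calls, annotations = NULL, stratum,
                               location_test = c("kruskal", "t"),
                               contingency_method = "fisher_exact") {
  location_test <- match.arg(location_test)
  df <- as.data.frame(calls)
  if (!is.null(annotations))
    df <- merge(df, annotations, by = c("chrom", "pos", "ref", "alt"),
                all.x = TRUE, sort = FALSE)
  if (!stratum %in% names(df))
    abort_usage(sprintf("unknown grouping key '%s'", stratum))
  df <- df[!is.na(df[[stratum]]), , drop = FALSE]
  g <- as.character(df[[stratum]])
  levels_g <- sort(unique(g))
  groups <- split(df$v_rd, factor(g, levels = levels_g))
  class_counts <- table(factor(g, levels = levels_g),
                        factor(df$call, levels = CALL_LEVELS))
  location <- NULL
  contingency <- NULL
  if (length(levels_g) >= 2) {
    location <- if (location_test == "kruskal") {
      kruskal_wallis(groups)
    } else {
      pairs <- utils::combn(levels_g, 2, simplify = FALSE)
      do.call(rbind, lapply(pairs, function(pr) {
        tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]])
        data.frame(group_a = pr[1], group_b = pr[2],
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   stringsAsFactors = FALSE)
      }))
    }
    pairs <- utils::combn(levels_g, 2, simplify = FALSE)
    rows <- list()
    for (pr in pairs) for (cls in c("SOM_E", "SOM_L")) {
      tab <- rbind(
        c(class_counts[pr[1], cls], sum(class_counts[pr[1], ]) - class_counts[pr[1], cls]),
        c(class_counts[pr[2], cls], sum(class_counts[pr[2], ]) - class_counts[pr[2], cls])
      )
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = pr[1], group_b = pr[2], class = cls,
        p_value = contingency_2x2(tab, contingency_method),
        stringsAsFactors = FALSE)
    }
    contingency <- do.call(rbind, rows)
    contingency$q_value <- bh_adjust(contingency$p_value)
  }
  structure(list(stratum = stratum, groups = groups,
                 class_counts = class_counts, location = location,
                 contingency = contingency),
            class = "stratified_summary")
}

#' @export
print.stratified_summary <- function(x, ...) {
  cat(sprintf("Stratified summary by '%s' (%d group(s))\n",
              x$stratum, length(x$groups)))
  med <- vapply(x$groups, stats::median, numeric(1))
  for (g in names(x$groups))
    cat(sprintf("  %s: n = %d, median V_RD = %.3f\n",
                g, length(x$groups[[g]]), med[g]))
  if (!is.null(x$location) && is.list(x$location) && !is.data.frame(x$location))
    cat(sprintf("  Kruskal-Wallis: H = %.3f, df = %d, p = %.3g\n",
                x$location$statistic, x$location$df, x$location$p_value))
  invisible(x)
}
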