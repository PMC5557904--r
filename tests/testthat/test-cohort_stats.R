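test_that("recurrence_spectrum reproduces printed-cohort arithmetic", {
  calls <- spectrum_calls(PRINTED_SPECTRUM)
  sp <- recurrence_spectrum(calls)
  expect_equal(sp$unique_count, 1139L)
  expect_equal(sp$total_count, 1238L)
  expect_equal(round(100 * sp$singleton_fraction), 94)
  expect_equal(unname(sp$multiplicity_histogram[as.character(2:7)]),
               c(44L, 12L, 4L, 2L, 1L, 1L))
})

test_that("recurrence_spectrum handles degenerate cohorts", {
  one <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:5,
                    ref = "A", alt = "C")
  sp <- recurrence_spectrum(one)
  expect_equal(sp$singleton_fraction, 1)
  expect_equal(sp$total_count, sp$unique_count)

  shared <- rbind(one, data.frame(sample_id = "S2", chrom = "chr1", pos = 1L,
                                  ref = "A", alt = "C"))
  sp2 <- recurrence_spectrum(shared)
  expect_equal(unname(sp2$multiplicity_histogram["2"]), 1L)
  expect_equal(sp2$unique_count, 5L)
  expect_equal(sp2$total_count, 6L)
})

test_that("spectrum conservation: totals match distinct keys and rows", {
  set.seed(41)
  calls <- data.frame(
    sample_id = sample(sprintf("S%d", 1:8), 300, TRUE),
    chrom = "chr1", pos = sample(1:120, 300, TRUE), ref = "A", alt = "C")
  calls <- calls[!duplicated(calls), ]
  sp <- recurrence_spectrum(calls)
  expect_equal(sp$total_count, nrow(calls))
  expect_equal(sp$unique_count, length(unique(calls$pos)))
  expect_equal(sum(sp$multiplicity_histogram), sp$unique_count)
  m <- as.integer(names(sp$multiplicity_histogram))
  expect_equal(sum(m * sp$multiplicity_histogram), sp$total_count)
})

test_that("spearman_rho matches the rank formula and handles missing pairs", {
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)
  expect_equal(spearman_rho(1:6, -(1:6)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)  # 1 - 6*4/60
  expect_error(spearman_rho(1:5, 1:4), class = "somase_precondition_error")
  expect_error(spearman_rho(c(1, 2, NA), c(1, NA, 3)),
               class = "somase_insufficient_data_error")
  # NA pairs dropped pairwise, result equals the complete-case correlation
  x <- c(1, 2, 3, 4, 5, NA); y <- c(2, 1, 4, 3, NA, 6)
  expect_equal(spearman_rho(x, y), spearman_rho(1:4, c(2, 1, 4, 3)))
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base)
    expect_equal(spearman_rho(x, y^3 + 5 * y), base)
    expect_equal(cor(x, y, method = "spearman"), base)  # reference oracle
  }
})

test_that("kruskal_wallis matches hand-computed H and is label-symmetric", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)   # rank sums (6, 15, 24)
  expect_equal(kw$df, 2)
  kw2 <- kruskal_wallis(list(c(1, 3), c(2, 4)))
  expect_equal(kw2$statistic, 0.6)
  perm <- kruskal_wallis(list(c(7, 8, 9), c(1, 2, 3), c(4, 5, 6)))
  expect_equal(perm$statistic, kw$statistic)
  expect_equal(perm$p_value, kw$p_value)
  expect_error(kruskal_wallis(list(1:3)), class = "somase_precondition_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))),
               class = "somase_precondition_error")
})

test_that("kruskal_wallis agrees with the reference implementation under ties", {
  set.seed(43)
  for (i in 1:15) {
    g <- lapply(1:3, function(j) sample(1:6, sample(4:12, 1), replace = TRUE))
    got <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("permutation p-mode is seeded and concordant with chi-square", {
  g <- list(c(1.2, 3.4, 2.2, 8.1), c(5.5, 9.9, 7.3, 6.1))
  a <- kruskal_wallis(g, p_method = "permutation", n_perm = 999, seed = 7)
  b <- kruskal_wallis(g, p_method = "permutation", n_perm = 999, seed = 7)
  expect_equal(a$p_value, b$p_value)
  expect_lt(abs(a$p_value - kruskal_wallis(g)$p_value), 0.1)
})

test_that("fisher exact matches enumeration and frozen values", {
  expect_equal(contingency_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(contingency_2x2(matrix(c(5, 0, 0, 5), 2)), 0.0079365079,
               tolerance = 1e-8)  # 2 / C(10,5)
  expect_error(contingency_2x2(matrix(0L, 2, 2)),
               class = "somase_precondition_error")
})

test_that("fisher p equals the reference for all tables with total n <= 12", {
  for (n in 1:12) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts$d <- n - parts$a - parts$b - parts$c
    parts <- parts[parts$d >= 0, ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(unlist(parts[i, ]), 2, 2, byrow = TRUE)
      if (sum(tab) == 0) next
      expect_equal(contingency_2x2(tab, "fisher_exact"),
                   fisher.test(tab)$p.value, tolerance = 1e-10)
    }
  }
})

test_that("chi-square takes the Yates path exactly when a cell is below 5", {
  tab <- matrix(c(3, 6, 7, 4), 2, 2)   # cell 3 < 5 -> Yates
  n <- sum(tab)
  chi <- n * (abs(3 * 4 - 7 * 6) - n / 2)^2 / (10 * 10 * 9 * 11)
  expect_equal(contingency_2x2(tab, "chi2_yates_auto"),
               pchisq(chi, 1, lower.tail = FALSE))
  expect_equal(contingency_2x2(tab, "chi2_yates_auto"),
               suppressWarnings(chisq.test(tab, correct = TRUE)$p.value))
  big <- matrix(c(20, 30, 25, 15), 2, 2)  # all cells >= 5 -> plain Pearson
  expect_equal(contingency_2x2(big, "chi2_yates_auto"),
               suppressWarnings(chisq.test(big, correct = FALSE)$p.value))
})

test_that("stratified_summary groups, counts and tests across strata", {
  set.seed(44)
  n <- 60
  calls <- data.frame(
    sample_id = "S1", chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
    vaf_tdna = 0.3, vaf_trna = 0.3,
    v_rd = c(rexp(n / 2, 1), rexp(n / 2, 1 / 3)),  # group B shifted up
    p_value = runif(n), q_value = runif(n),
    call = sample(c("SOM_E", "SOM_L", "EXPRESSED_BALANCED"), n, TRUE),
    func_class = rep(c("missense", "non-coding"), each = n / 2),
    stringsAsFactors = FALSE)
  sm <- stratified_summary(calls, stratum = "func_class")
  expect_equal(sum(lengths(sm$groups)), n)
  expect_equal(sum(sm$class_counts), n)
  expect_gt(sm$location$statistic, 0)
  expect_true(all(sm$contingency$q_value >= sm$contingency$p_value - 1e-12))
  expect_error(stratified_summary(calls, stratum = "nope"),
               class = "somase_usage_error")

  one <- calls; one$func_class <- "missense"
  sm1 <- stratified_summary(one, stratum = "func_class")
  expect_null(sm1$location)            # single stratum: summary only
  expect_null(sm1$contingency)

  same <- calls; same$v_rd <- rep(rexp(n / 2), 2)
  sm2 <- stratified_summary(same, stratum = "func_class")
  expect_equal(sm2$location$statistic, 0, tolerance = 1e-10)
})

test_that("stratified_summary detects a known stochastic dominance shift", {
  set.seed(45)
  n <- 400
  calls <- data.frame(
    sample_id = "S1", chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
    vaf_tdna = 0.3, vaf_trna = 0.3,
    v_rd = c(rexp(n / 2, 1), rexp(n / 2, 1) + 0.75),
    p_value = 0.5, q_value = 0.5, call = "EXPRESSED_BALANCED",
    func_class = rep(c("non-coding", "missense"), each = n / 2),
    stringsAsFactors = FALSE)
  sm <- stratified_summary(calls, stratum = "func_class")
  expect_lt(sm$location$p_value, 0.001)
  expect_gt(median(sm$groups[["missense"]]),
            median(sm$groups[["non-coding"]]))
  tt <- stratified_summary(calls, stratum = "func_class", location_test = "t")
  expect_s3_class(tt$location, "data.frame")
  expect_lt(tt$location$p_value, 0.001)
})
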