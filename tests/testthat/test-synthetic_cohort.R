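test_that("identical configurations give identical cohorts", {
  cfg <- sim_config(n_samples = 6, sites_per_sample = 15, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(sim_config(n_samples = 6, sites_per_sample = 15,
                                   seed = 10))
  expect_false(identical(a$records, c2$records))
})

test_that("class fractions honour the configuration", {
  no_e <- generate_cohort(sim_config(n_samples = 8, sites_per_sample = 25,
                                     frac_som_e = 0, seed = 2))
  expect_false(any(no_e$truth$true_class == "SOM_E"))

  cfg <- sim_config(n_samples = 40, sites_per_sample = 50, seed = 3)
  co <- generate_cohort(cfg)
  clean <- co$truth$true_class %in% c("SOM_E", "SOM_L", "BALANCED")
  n <- sum(clean)
  for (cls in c("SOM_E", "SOM_L")) {
    frac <- cfg[[if (cls == "SOM_E") "frac_som_e" else "frac_som_l"]]
    emp <- mean(co$truth$true_class[clean] == cls)
    se <- sqrt(frac * (1 - frac) / n)
    expect_lt(abs(emp - frac), 3 * se + 1e-9)
  }
})

test_that("degenerate noise: seq_error 0 makes SOM_E RNA purely variant", {
  co <- generate_cohort(sim_config(n_samples = 10, sites_per_sample = 30,
                                   seq_error = 0, frac_som_e = 0.5,
                                   frac_som_l = 0.2, seed = 4))
  e <- co$truth$true_class == "SOM_E"
  expect_gt(sum(e), 0)
  expect_true(all(co$records$tr_ref[e] == 0L))
  expect_true(all(co$records$nd_var[e] == 0L))
  l <- co$truth$true_class == "SOM_L"
  expect_true(all(co$records$tr_var[l] == 0L))
})

test_that("sites planted in CNA or imprinted intervals are always filtered out", {
  co <- generate_cohort(sim_config(n_samples = 15, sites_per_sample = 40,
                                   frac_in_cna = 0.15, frac_in_imprinted = 0.1,
                                   seed = 5))
  out <- apply_filters(co$records, co$intervals)
  planted <- co$truth$in_cna | co$truth$in_imprinted
  expect_gt(sum(planted), 0)
  expect_true(all(!out$verdicts$retained[planted]))
  # and the exhaustive retained-set contract holds
  kept <- out$retained
  cfg <- filter_config()
  expect_true(all(kept$td_ref + kept$td_var >= cfg$min_depth))
  expect_true(all(kept$tr_ref + kept$tr_var >= cfg$min_depth))
  expect_true(all(kept$nd_var <= cfg$germline_max_var_reads))
  expect_true(all(kept$nr_var <= cfg$germline_max_var_reads))
  tvaf <- kept$td_var / (kept$td_ref + kept$td_var)
  expect_true(all(tvaf > 0 & tvaf < 1))
})

test_that("with zero overdispersion balanced RNA counts are exactly binomial", {
  co <- generate_cohort(sim_config(n_samples = 100, sites_per_sample = 100,
                                   rna_overdispersion = 0,
                                   frac_som_e = 0, frac_som_l = 0,
                                   frac_germline_contam = 0, frac_in_cna = 0,
                                   frac_in_imprinted = 0, seed = 6))
  r <- co$records
  n <- r$tr_ref + r$tr_var
  keep <- n > 0
  p <- co$truth$true_rna_var_fraction[keep]
  expect_true(all(p == co$config$purity / 2))
  # randomized PIT: exactly uniform iff counts are binomial(n, p)
  set.seed(60)
  u <- pbinom(r$tr_var[keep] - 1, n[keep], p) +
    runif(sum(keep)) * dbinom(r$tr_var[keep], n[keep], p)
  ks <- ks.test(u, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("copula calibration hits the target rank correlation", {
  cfg <- sim_config(n_samples = 100, sites_per_sample = 50, score_rho = 0.30,
                    seed = 7)
  co <- generate_cohort(cfg)   # 5,000 sites
  m <- merge(co$truth, co$annotations, by = c("chrom", "pos", "ref", "alt"))
  rho <- spearman_rho(m$cadd, m$true_rna_var_fraction)
  expect_lt(abs(rho - 0.30), 0.05)

  neg <- generate_cohort(sim_config(n_samples = 30, sites_per_sample = 40,
                                    score_rho = -0.4, seed = 8))
  mn <- merge(neg$truth, neg$annotations, by = c("chrom", "pos", "ref", "alt"))
  expect_lt(abs(spearman_rho(mn$cadd, mn$true_rna_var_fraction) + 0.4), 0.06)
})

test_that("cohort files round-trip through the io readers", {
  co <- generate_cohort(sim_config(n_samples = 5, sites_per_sample = 12,
                                   seed = 11))
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  expect_identical(as.data.frame(read_quad_counts(paths[["counts"]])),
                   as.data.frame(co$records))
  iv <- rbind(read_intervals(paths[["imprinted"]], "bed"),
              read_intervals(paths[["cna"]], "seg"))
  expect_equal(sort(iv$start), sort(co$intervals$start))
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(co$annotations))
  expect_equal(sum(is.na(ann$gerp)), sum(is.na(co$annotations$gerp)))
})

test_that("truth_confusion joins, tabulates and scores calls", {
  co <- generate_cohort(sim_config(n_samples = 10, sites_per_sample = 30,
                                   seed = 12))
  out <- apply_filters(co$records, co$intervals)
  calls <- call_expression_status(out$retained)
  tc <- truth_confusion(calls, co$truth)
  # contaminant truth classes (germline slipping the filters) are excluded
  expect_lte(sum(tc$confusion), nrow(calls))
  expect_gt(sum(tc$confusion), 0)
  expect_equal(dim(tc$confusion), c(3L, 3L))

  # perfect calls give an identity confusion matrix
  perfect <- calls
  m <- match(paste(calls$sample_id, calls$chrom, calls$pos),
             paste(co$truth$sample_id, co$truth$chrom, co$truth$pos))
  perfect$call <- ifelse(co$truth$true_class[m] == "BALANCED",
                         "EXPRESSED_BALANCED", co$truth$true_class[m])
  tcp <- truth_confusion(perfect, co$truth)
  expect_equal(sum(diag(tcp$confusion)), sum(tcp$confusion))
  expect_true(all(tcp$rates$sensitivity[tcp$rates$n_pos > 0] == 1))

  # all-balanced calls have zero sensitivity for the extremes
  lazy <- calls; lazy$call <- "EXPRESSED_BALANCED"
  tcl <- truth_confusion(lazy, co$truth)
  ext <- tcl$rates[tcl$rates$class != "BALANCED", ]
  expect_true(all(ext$sensitivity[ext$n_pos > 0] == 0))

  orphan <- calls[1, ]; orphan$pos <- orphan$pos + 1L
  expect_error(truth_confusion(orphan, co$truth), class = "somase_join_error")
})
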