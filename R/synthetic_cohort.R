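#' Simulation configuration
#'
#' Parameters of the matched four-way read-count simulator. Defaults emulate
#' a breast-tumor cohort of the kind the pipeline targets: 72 samples with a
#' mean of 17 analyzable somatic point mutations each, tumor purity 0.6,
#' exome/transcriptome coverage around 80x/60x with negative-binomial
#' spread, per-base sequencing error 1e-3, and expression-extreme fractions
#' of 5% over-expressed (SOM-E) and 38% lost (SOM-L) among clean somatic
#' sites.
#'
#' @param n_samples Number of patients.
#' @param sites_per_sample Somatic candidate sites emitted per sample.
#' @param purity Tumor cell fraction in (0, 1]; a clonal heterozygous
#'   diploid mutation then has expected tumor-DNA VAF `purity / 2`.
#' @param coverage_mean_dna,coverage_mean_rna Mean sequencing depth of the
#'   DNA and RNA datasets.
#' @param coverage_dispersion Negative-binomial size parameter for depth
#'   (smaller = more overdispersed).
#' @param seq_error Per-base sequencing error rate; variant reads in normal
#'   tissue, and residual reads at mono-allelic RNA sites, arise at this rate.
#' @param frac_som_e,frac_som_l Fractions of clean somatic sites whose true
#'   RNA state is over-expressed (variant fraction `1 - seq_error`) or lost
#'   (`seq_error`); the remainder are balanced.
#' @param rna_overdispersion Beta-binomial intra-class correlation of
#'   balanced-site RNA counts around the site's true DNA VAF; `0` gives
#'   exactly binomial counts (the null used for calibration tests).
#' @param frac_germline_contam Fraction of sites that are germline
#'   heterozygotes leaking through upstream calling (VAF ~ 0.5 in all four
#'   datasets).
#' @param frac_in_cna,frac_in_imprinted Fractions of sites planted inside a
#'   generated copy-number segment (`|seg_mean|` 0.3-1.0) or imprinted
#'   region; the filters must remove these.
#' @param score_rho Target Spearman correlation between the primary
#'   pathogenicity score (`cadd`) and the true RNA variant fraction,
#'   realised by a Gaussian-copula construction calibrated on the generated
#'   cohort itself.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_samples = 72L, sites_per_sample = 17L,
                       purity = 0.6,
                       coverage_mean_dna = 80, coverage_mean_rna = 60,
                       coverage_dispersion = 4,
                       seq_error = 0.001,
                       frac_som_e = 0.05, frac_som_l = 0.38,
                       rna_overdispersion = 0.05,
                       frac_germline_contam = 0.05,
                       frac_in_cna = 0.05, frac_in_imprinted = 0.02,
                       score_rho = 0.30, seed = 1L) {
  fracs <- c(frac_som_e = frac_som_e, frac_som_l = frac_som_l,
             frac_germline_contam = frac_germline_contam,
             frac_in_cna = frac_in_cna, frac_in_imprinted = frac_in_imprinted,
             seq_error = seq_error)
  if (any(fracs < 0 | fracs > 1)) abort_config("fractions must lie in [0, 1]")
  if (frac_som_e + frac_som_l > 1)
    abort_config("frac_som_e + frac_som_l must not exceed 1")
  if (frac_germline_contam + frac_in_cna + frac_in_imprinted > 1)
    abort_config("contaminant and interval fractions must not exceed 1 in total")
  if (purity <= 0 || purity > 1) abort_config("purity must lie in (0, 1]")
  if (coverage_mean_dna <= 0 || coverage_mean_rna <= 0 || coverage_dispersion <= 0)
    abort_config("coverage parameters must be positive")
  if (rna_overdispersion < 0 || rna_overdispersion >= 1)
    abort_config("rna_overdispersion must lie in [0, 1)")
  if (abs(score_rho) > 0.99) abort_config("score_rho must lie in [-0.99, 0.99]")
  structure(list(
    n_samples = as.integer(n_samples),
    sites_per_sample = as.integer(sites_per_sample),
    purity = purity,
    coverage_mean_dna = coverage_mean_dna,
    coverage_mean_rna = coverage_mean_rna,
    coverage_dispersion = coverage_dispersion,
    seq_error = seq_error,
    frac_som_e = frac_som_e, frac_som_l = frac_som_l,
    rna_overdispersion = rna_overdispersion,
    frac_germline_contam = frac_germline_contam,
    frac_in_cna = frac_in_cna, frac_in_imprinted = frac_in_imprinted,
    score_rho = score_rho, seed = as.integer(seed)
  ), class = "sim_config")
}

# Coordinate bands keeping site classes spatially disjoint by design:
# imprinted regions in [1e6, 2e7], CNA segments in [2.1e7, 4.5e7], and all
# other sites in [5e7, 1.5e8], so clean sites never touch an exclusion
# interval and planted sites always do.
SIM_CHROMS <- paste0("chr", 1:22)
BAND_IMPRINTED <- c(1e6, 2e7)
BAND_CNA <- c(2.1e7, 4.5e7)
BAND_CLEAN <- c(5e7, 1.5e8)

TRUE_CLASSES <- c("SOM_E", "SOM_L", "BALANCED", "GERMLINE",
                  "CNA_SITE", "IMPRINTED_SITE")

#' Generate a matched four-way read-count cohort with ground truth
#'
#' Draws a full synthetic cohort: per-site read depths
#' (negative-binomial), tumor-DNA variant counts diluted by purity
#' (expected VAF `purity/2` at clonal heterozygous diploid sites), tumor-RNA
#' counts reflecting each site's true expression state (mono-allelic variant
#' for SOM-E truth, mono-allelic reference for SOM-L, beta-binomial around
#' the true DNA VAF for balanced sites), sequencing-error reads in normal
#' tissue, germline-heterozygote contaminants, exclusion intervals with
#' sites planted inside them, and an annotation table whose `cadd` score has
#' a calibrated Spearman correlation `score_rho` with the true RNA variant
#' fraction. Identical configurations (including seed) yield identical
#' cohorts.
#'
#' @param config A [sim_config()].
#' @return A list of class `somase_cohort`: `records` (a `somase_records`
#'   table), `intervals`, `annotations`, `truth` (per-record true class and
#'   parameters), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  with_private_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_total <- config$n_samples * config$sites_per_sample
  sample_id <- rep(sprintf("S%03d", seq_len(config$n_samples)),
                   each = config$sites_per_sample)

  # exclusion intervals ----------------------------------------------------
  n_imp <- 12L
  imprinted <- data.frame(
    chrom = sample(SIM_CHROMS, n_imp, replace = TRUE),
    start = as.integer(round(stats::runif(n_imp, BAND_IMPRINTED[1], BAND_IMPRINTED[2] - 6e5))),
    label = "imprinted", value = NA_real_, sample = NA_character_,
    stringsAsFactors = FALSE
  )
  imprinted$end <- imprinted$start + as.integer(round(stats::runif(n_imp, 1e5, 5e5)))
  cna <- do.call(rbind, lapply(unique(sample_id), function(s) {
    k <- 3L
    start <- as.integer(round(stats::runif(k, BAND_CNA[1], BAND_CNA[2] - 3e6)))
    affected <- data.frame(
      chrom = sample(SIM_CHROMS, k, replace = TRUE),
      start = start, end = start + as.integer(round(stats::runif(k, 5e5, 2.5e6))),
      label = "CNA",
      value = stats::runif(k, 0.3, 1.0) * sample(c(-1, 1), k, replace = TRUE),
      sample = s, stringsAsFactors = FALSE
    )
    nstart <- as.integer(round(stats::runif(2L, BAND_CLEAN[1], BAND_CLEAN[2] - 3e6)))
    neutral <- data.frame(  # copy-neutral segments: must NOT exclude sites
      chrom = sample(SIM_CHROMS, 2L, replace = TRUE),
      start = nstart, end = nstart + as.integer(round(stats::runif(2L, 5e5, 2.5e6))),
      label = "CNA", value = stats::runif(2L, -0.05, 0.05),
      sample = s, stringsAsFactors = FALSE
    )
    rbind(affected, neutral)
  }))
  intervals <- rbind(imprinted[c("chrom", "start", "end", "label", "value", "sample")],
                     cna[c("chrom", "start", "end", "label", "value", "sample")])
  class(intervals) <- c("somase_intervals", "data.frame")

  # true classes -----------------------------------------------------------
  u <- stats::runif(n_total)
  p_g <- config$frac_germline_contam
  p_c <- config$frac_in_cna
  p_i <- config$frac_in_imprinted
  true_class <- rep("BALANCED", n_total)
  true_class[u < p_g] <- "GERMLINE"
  true_class[u >= p_g & u < p_g + p_c] <- "CNA_SITE"
  true_class[u >= p_g + p_c & u < p_g + p_c + p_i] <- "IMPRINTED_SITE"
  clean <- which(u >= p_g + p_c + p_i)
  v <- stats::runif(length(clean))
  true_class[clean[v < config$frac_som_e]] <- "SOM_E"
  true_class[clean[v >= config$frac_som_e &
                   v < config$frac_som_e + config$frac_som_l]] <- "SOM_L"

  # positions and alleles --------------------------------------------------
  chrom <- character(n_total)
  pos <- integer(n_total)
  for (i in seq_len(n_total)) {
    if (true_class[i] == "IMPRINTED_SITE") {
      j <- sample.int(nrow(imprinted), 1L)
      chrom[i] <- imprinted$chrom[j]
      pos[i] <- as.integer(round(stats::runif(1, imprinted$start[j], imprinted$end[j])))
    } else if (true_class[i] == "CNA_SITE") {
      segs <- cna[cna$sample == sample_id[i] & abs(cna$value) > 0.1, , drop = FALSE]
      j <- sample.int(nrow(segs), 1L)
      chrom[i] <- segs$chrom[j]
      pos[i] <- as.integer(round(stats::runif(1, segs$start[j], segs$end[j])))
    } else {
      chrom[i] <- sample(SIM_CHROMS, 1L)
      pos[i] <- as.integer(round(stats::runif(1, BAND_CLEAN[1], BAND_CLEAN[2])))
    }
  }
  # nudge the rare random (sample, chrom, pos) collision apart; offsets are
  # small enough to stay inside any planted interval
  repeat {
    dup <- duplicated(paste(sample_id, chrom, pos, sep = "\r"))
    if (!any(dup)) break
    pos[dup] <- pos[dup] + sample.int(50L, sum(dup), replace = TRUE)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  # depths ------------------------------------------------------------------
  rdepth <- function(mu) stats::rnbinom(n_total, size = config$coverage_dispersion, mu = mu)
  nd_n <- rdepth(config$coverage_mean_dna)
  nr_n <- rdepth(config$coverage_mean_rna)
  td_n <- rdepth(config$coverage_mean_dna)
  tr_n <- rdepth(config$coverage_mean_rna)

  # true allelic parameters -------------------------------------------------
  err <- config$seq_error
  is_germ <- true_class == "GERMLINE"
  true_dna_vaf <- ifelse(is_germ, 0.5, config$purity / 2)
  rho <- config$rna_overdispersion
  true_rna_frac <- numeric(n_total)
  for (i in seq_len(n_total)) {
    true_rna_frac[i] <- switch(true_class[i],
      SOM_E = 1 - err,
      SOM_L = err,
      GERMLINE = 0.5,
      { # BALANCED / CNA_SITE / IMPRINTED_SITE: RNA mirrors DNA, with
        # optional beta overdispersion around the true DNA VAF
        mu <- true_dna_vaf[i]
        if (rho > 0) stats::rbeta(1, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
        else mu
      })
  }

  # read counts -------------------------------------------------------------
  norm_p <- ifelse(is_germ, 0.5, err)
  nd_var <- stats::rbinom(n_total, nd_n, norm_p)
  nr_var <- stats::rbinom(n_total, nr_n, norm_p)
  td_var <- stats::rbinom(n_total, td_n, true_dna_vaf)
  tr_var <- stats::rbinom(n_total, tr_n, true_rna_frac)

  records <- variant_records(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    nd_ref = nd_n - nd_var, nd_var = nd_var,
    nr_ref = nr_n - nr_var, nr_var = nr_var,
    td_ref = td_n - td_var, td_var = td_var,
    tr_ref = tr_n - tr_var, tr_var = tr_var,
    sample_id = sample_id
  )

  # annotations with copula-calibrated score ---------------------------------
  z <- calibrated_score(true_rna_frac, config$score_rho)
  shared <- 0.5 * z + sqrt(1 - 0.25) * stats::rnorm(n_total)
  n_genes <- max(20L, round(n_total * 0.75))
  gene_idx <- sample.int(n_genes, n_total, replace = TRUE)
  in_cgc_gene <- stats::runif(n_genes) < 0.08
  mode_gene <- sample(c("dominant", "recessive"), n_genes, replace = TRUE,
                      prob = c(0.6, 0.4))
  func_class <- sample(FUNC_CLASSES, n_total, replace = TRUE,
                       prob = c(0.55, 0.35, 0.05, 0.05))
  fathmm_score <- 0.8 * shared + 0.6 * stats::rnorm(n_total)
  annotations <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = sprintf("%s%04d", ifelse(in_cgc_gene[gene_idx], "CGC", "GENE"), gene_idx),
    func_class = func_class,
    cadd = 15 + 6 * z,
    fathmm_score = fathmm_score,
    fathmm_call = ifelse(fathmm_score > 0.8, "pathogenic", "neutral"),
    gerp = 2 + 2 * (0.6 * shared + 0.8 * stats::rnorm(n_total)),
    polyphen = stats::pnorm(0.7 * shared + 0.7 * stats::rnorm(n_total)),
    grantham = round(stats::runif(n_total, 5, 215)),
    phast = stats::pnorm(0.5 * shared + 0.9 * stats::rnorm(n_total)),
    in_cancer_gene_list = in_cgc_gene[gene_idx],
    molecular_mode = mode_gene[gene_idx],
    stringsAsFactors = FALSE
  )
  for (col in c("fathmm_score", "gerp", "polyphen", "grantham", "phast"))
    annotations[[col]][stats::runif(n_total) < 0.08] <- NA_real_
  # duplicated sites across samples share one annotation row
  annotations <- annotations[!duplicated(site_key(annotations)), , drop = FALSE]

  truth <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    true_class = true_class,
    true_dna_vaf = true_dna_vaf,
    true_rna_var_fraction = true_rna_frac,
    in_cna = true_class == "CNA_SITE",
    in_imprinted = true_class == "IMPRINTED_SITE",
    stringsAsFactors = FALSE
  )

  structure(list(records = records, intervals = intervals,
                 annotations = annotations, truth = truth, config = config),
            class = "somase_cohort")
}

# Gaussian-copula score with calibrated Spearman correlation to f.
# The latent normal quantile of f's midranks is mixed with independent
# noise; the mixing weight is solved (common random numbers, so the
# objective is deterministic and monotone) so the realised rank correlation
# on this very cohort equals the target.
calibrated_score <- function(f, rho_target) {
  n <- length(f)
  eps <- stats::rnorm(n)
  if (rho_target == 0 || length(unique(f)) < 3 || n < 8) return(eps)
  q <- stats::qnorm(rank(f, ties.method = "average") / (n + 1))
  g <- function(r) spearman_rho(r * q + sqrt(1 - r^2) * eps, f) - rho_target
  lo <- -0.999; hi <- 0.999
  if (g(lo) > 0 || g(hi) < 0) return(if (rho_target > 0) q else -q)
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-6)$root
  r * q + sqrt(1 - r^2) * eps
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the dialects the readers consume: `counts.tsv`
#' ([read_quad_counts()]), `imprinted.bed` and `cna.seg`
#' ([read_intervals()]), `annotations.tsv` ([read_annotations()]) and
#' `truth.tsv`, so the simulator doubles as a fixture generator.
#'
#' @param cohort A `somase_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             imprinted = file.path(dir, "imprinted.bed"),
             cna = file.path(dir, "cna.seg"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(as.data.frame(cohort$records)[RECORD_COLS], paths["counts"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- cohort$intervals[cohort$intervals$label != "CNA", , drop = FALSE]
  bed <- data.frame(chrom = imp$chrom, start = imp$start - 1L, end = imp$end,
                    name = imp$label)
  utils::write.table(bed, paths["imprinted"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cna <- cohort$intervals[cohort$intervals$label == "CNA", , drop = FALSE]
  seg <- data.frame(sample = cna$sample, chrom = cna$chrom, start = cna$start,
                    end = cna$end, num_mark = NA_integer_, seg_mean = cna$value)
  utils::write.table(seg, paths["cna"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Confusion matrix of calls against simulation truth
#'
#' Joins expression calls to the simulator's truth table by (sample, site),
#' restricts to truth classes the caller can express (SOM_E, SOM_L,
#' BALANCED), and tabulates the 3x3 confusion together with per-class
#' sensitivity and specificity with exact (Clopper-Pearson) 95% intervals.
#'
#' @param calls An `expression_calls` data frame.
#' @param truth The `truth` element of a `somase_cohort`.
#' @return A list: `confusion` (truth x called), `rates` (per class:
#'   sensitivity, specificity, with confidence bounds and denominators).
#' @export
truth_confusion <- function(calls, truth) {
  ck <- paste(calls$sample_id, site_key(calls), sep = "\r")
  tk <- paste(truth$sample_id, site_key(truth), sep = "\r")
  orphans <- setdiff(ck, tk)
  if (length(orphans))
    abort_join(sprintf("calls absent from truth: %s",
                       paste(utils::head(gsub("\r", " ", orphans), 5), collapse = "; ")))
  m <- match(ck, tk)
  true_cls <- truth$true_class[m]
  keep <- true_cls %in% c("SOM_E", "SOM_L", "BALANCED")
  called <- ifelse(calls$call == "EXPRESSED_BALANCED", "BALANCED", calls$call)
  lv <- c("SOM_E", "SOM_L", "BALANCED")
  confusion <- table(truth = factor(true_cls[keep], levels = lv),
                     called = factor(called[keep], levels = lv))
  rates <- do.call(rbind, lapply(lv, function(cls) {
    tp <- confusion[cls, cls]
    pos <- sum(confusion[cls, ])
    fp <- sum(confusion[, cls]) - tp
    neg <- sum(confusion) - pos
    sens_ci <- if (pos > 0) stats::binom.test(tp, pos)$conf.int else c(NA, NA)
    spec_ci <- if (neg > 0) stats::binom.test(neg - fp, neg)$conf.int else c(NA, NA)
    data.frame(class = cls,
               sensitivity = if (pos > 0) tp / pos else NA_real_, n_pos = pos,
               sens_lo = sens_ci[1], sens_hi = sens_ci[2],
               specificity = if (neg > 0) (neg - fp) / neg else NA_real_, n_neg = neg,
               spec_lo = spec_ci[1], spec_hi = spec_ci[2],
               stringsAsFactors = FALSE)
  }))
  list(confusion = confusion, rates = rates)
}
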