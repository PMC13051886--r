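# Replicated evaluation harnesses: each runs the package's own pipeline on
# seeded synthetic data and reports calibration / recovery summaries. They
# back both the acceptance checks and the analysis drivers.

#' Type-I calibration of the bulk moderated-t stage on null data
#'
#' Simulates miRNA matrices with zero planted effects (batch effects on) and
#' runs the moderated t-test with Storey q-values.
#'
#' @param n_seeds replicate count (default 100).
#' @param base_seed first seed; replicates use consecutive seeds.
#' @param n_features,n_samples_per_group design (defaults 400 and 10).
#' @return list: `mean_frac_p05` (should sit near the nominal 0.05),
#'   `mean_frac_q05` (should be ~0), per-replicate vectors.
#' @export
eval_null_bulk_de <- function(n_seeds = 100, base_seed = 1,
                              n_features = 400, n_samples_per_group = 10) {
  frac_p <- frac_q <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = base_seed + i - 1, n_de = 0,
                      n_features = n_features,
                      n_samples_per_group = n_samples_per_group)
    m <- simulate_mirna_matrix(cfg)$matrix
    sv <- estimate_surrogate_variables(m, seed = cfg$seed)
    r <- moderated_t_test(m, covariates = sv)
    frac_p[i] <- mean(r$table$p < 0.05)
    frac_q[i] <- mean(r$table$q < 0.05)
  }
  list(mean_frac_p05 = mean(frac_p), mean_frac_q05 = mean(frac_q),
       frac_p = frac_p, frac_q = frac_q)
}

#' Type-I calibration of motif enrichment under random decoration
#'
#' Each draw decorates one motif over random genes and tests it against
#' random disjoint up/down DEG lists; no association is planted.
#'
#' @param n_draws number of seeded draws (default 1000).
#' @param base_seed first seed.
#' @param n_genes,n_carriers,n_de universe size, motif carriers, DEGs per
#'   direction.
#' @return list with `frac_p05` (fraction of motif tests with p < 0.05) and
#'   the pooled p-values.
#' @export
eval_null_site_enrichment <- function(n_draws = 1000, base_seed = 1,
                                      n_genes = 400, n_carriers = 40,
                                      n_de = 50) {
  universe <- sprintf("g%04d", seq_len(n_genes))
  ps <- numeric(0)
  for (i in seq_len(n_draws)) {
    set.seed(base_seed + i - 1)
    carriers <- sample(universe, n_carriers)
    de <- sample(universe, 2 * n_de)
    sites <- data.frame(motif = "ACGUACG", mirna = "miR-x", gene = carriers,
                        n_sites = 1, stringsAsFactors = FALSE)
    rows <- site_enrichment(sites, de[seq_len(n_de)], de[n_de + seq_len(n_de)],
                            universe, keep_all = TRUE)
    ps <- c(ps, rows$p)
  }
  list(frac_p05 = mean(ps < 0.05), p = ps)
}

#' Type-I calibration of pseudobulk NB quasi-likelihood tests
#'
#' Null single-cell cohorts (no planted programs, identical NB law in both
#' groups) are aggregated per donor and tested.
#'
#' @param n_seeds replicates (default 50).
#' @param base_seed first seed.
#' @param n_donors donors per group (default 6).
#' @param cells_per_donor cells per donor (default 50).
#' @param n_genes gene universe (default 2000).
#' @return list with `mean_frac_p05` and the per-replicate fractions.
#' @export
eval_null_pseudobulk <- function(n_seeds = 50, base_seed = 1, n_donors = 6,
                                 cells_per_donor = 50, n_genes = 2000) {
  fr <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = base_seed + i - 1, n_donors = n_donors,
                      cells_per_donor = cells_per_donor, n_genes_sc = n_genes,
                      program_frequencies = list(
                        control = c(Tc17 = 0, Treg = 0),
                        case = c(Tc17 = 0, Treg = 0)
                      ))
    sim <- simulate_single_cell(cfg)
    pb <- pseudobulk(sim$sce)
    r <- nb_ql_test(pb)
    fr[i] <- mean(r$table$p < 0.05)
  }
  list(mean_frac_p05 = mean(fr), frac_p = fr)
}

#' Sensitivity of the bulk DE stage on planted effects
#'
#' The power companion to [eval_null_bulk_de()]: 20 planted features of
#' effect 1.0 log2 among 400, 10 samples per group, noise 0.3.
#'
#' @param n_seeds replicates (default 20).
#' @param base_seed first seed.
#' @return list with `median_sensitivity` at q < 0.05 and per-seed values.
#' @export
eval_bulk_de_power <- function(n_seeds = 20, base_seed = 1) {
  sens <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = base_seed + i - 1, n_de = 20, effect_size = 1,
                      noise_sd = 0.3)
    sim <- simulate_mirna_matrix(cfg)
    r <- moderated_t_test(sim$matrix)
    hit <- r$table$feature[r$table$q < 0.05]
    sens[i] <- mean(sim$truth$de_features$feature %in% hit)
  }
  list(median_sensitivity = stats::median(sens), sensitivity = sens)
}

#' End-to-end recovery of planted suppressed miRNAs
#'
#' The headline integrative property: 10 suppressed miRNAs (effect -1 log2,
#' suppression 1, 60 targets each) in a 4000-gene universe with 10 samples
#' per group; a replicate succeeds when at least `min_recovered` planted
#' miRNAs emerge from the DE -> site-enrichment -> intersection chain with
#' estimated activity "Downregulated" at adjusted p < 0.05.
#'
#' @param n_seeds replicates (default 20).
#' @param base_seed first seed.
#' @param min_recovered per-replicate success bar (default 8 of 10).
#' @return list: `success_rate`, `mean_recovered`, per-seed recovered counts.
#' @export
eval_integrative_recovery <- function(n_seeds = 20, base_seed = 1,
                                      min_recovered = 8) {
  recovered <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = base_seed + i - 1, n_de = 10,
                      de_direction = "down", effect_size = 1,
                      suppression = 1, targets_per_mirna = 60, n_genes = 4000)
    mir <- simulate_mirna_matrix(cfg)
    mm <- filter_top_expressed(mir$matrix, min(400, nrow(mir$matrix$values)))
    sv <- estimate_surrogate_variables(mm, seed = cfg$seed)
    mde <- moderated_t_test(mm, covariates = sv)
    mh <- call_de(mde, q_max = 0.05, min_abs_fc = 1)

    tx <- simulate_regulated_transcriptome(cfg, mir$truth)
    gm <- filter_low_intensity(quantile_normalize(tx$matrix), 6)
    gde <- moderated_t_test(gm)
    gh <- call_de(gde, q_max = 0.1, min_abs_fc = 1.5)

    rows <- site_enrichment(tx$sites, gh$up, gh$down, rownames(gm$values),
                            adj_p_max = 0.05)
    dirs <- data.frame(
      mirna = c(mh$up, mh$down),
      direction = c(rep("up", length(mh$up)), rep("down", length(mh$down))),
      stringsAsFactors = FALSE
    )
    infl <- intersect_influential(rows, dirs)
    rec <- unique(unlist(strsplit(
      infl$mirnas[infl$estimated_activity == "Downregulated"], ",")))
    recovered[i] <- length(intersect(rec, unique(tx$truth$regulon$mirna)))
  }
  list(success_rate = mean(recovered >= min_recovered),
       mean_recovered = mean(recovered), recovered = recovered)
}

#' Quantification of a rare planted subpopulation across a synthetic cohort
#'
#' Tc17 frequencies of 2% (controls) vs 4% (cases), 12 donors per group and
#' 400 cells per donor: cells are gated, QC-filtered, AUC-scored against the
#' Tc17 signature, thresholded at 0.22, and donor fractions are compared with
#' Welch's t. A replicate succeeds when both estimated group means sit
#' within `tol_pp` percentage points of that cohort's true planted
#' frequencies (the realized per-donor fractions recorded in the generator's
#' truth, whose expectation is 2% / 4%) and the Welch p is below 0.05.
#'
#' @param n_seeds replicates (default 20).
#' @param base_seed first seed.
#' @param tol_pp tolerance in percentage points (default 1).
#' @return list: `success_rate`, mean estimated group frequencies, per-seed
#'   estimates and p-values.
#' @export
eval_subpopulation_quantification <- function(n_seeds = 20, base_seed = 1,
                                              tol_pp = 1) {
  est_control <- est_case <- pvals <- numeric(n_seeds)
  true_control <- true_case <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = base_seed + i - 1)
    sim <- simulate_single_cell(cfg)
    tr <- sim$truth$donor_frequencies
    true_control[i] <- mean(tr$Tc17[tr$group == "control"])
    true_case[i] <- mean(tr$Tc17[tr$group == "case"])
    sce <- qc_filter(gate_cd8(sim$sce))
    sc <- aucell_score(sce, cfg$signatures$Tc17, top_fraction = 0.05,
                       seed = cfg$seed)
    lab <- classify_cells(sc, default_auc_thresholds()[["Tc17"]])
    meta <- data.frame(
      cell = colnames(sce),
      donor = as.character(SummarizedExperiment::colData(sce)$donor),
      group = as.character(SummarizedExperiment::colData(sce)$group),
      stringsAsFactors = FALSE
    )
    fr <- compare_frequencies(lab, meta)
    means <- tapply(fr$fractions$fraction, fr$fractions$group, mean)
    est_control[i] <- means[["control"]]
    est_case[i] <- means[["case"]]
    pvals[i] <- fr$test$p
  }
  ok <- abs(est_control - true_control) <= tol_pp / 100 &
    abs(est_case - true_case) <= tol_pp / 100 &
    pvals < 0.05
  list(success_rate = mean(ok),
       mean_control = mean(est_control), mean_case = mean(est_case),
       est_control = est_control, est_case = est_case, p = pvals,
       true_control = true_control, true_case = true_case,
       nominal = c(control = 0.02, case = 0.04))
}

#' qPCR arithmetic round trip
#'
#' Exact efficiency and ddCt identities plus a Monte-Carlo recovery of a
#' planted 4-fold change at Ct noise 0.2 and 10 samples per group.
#'
#' @param seed generator seed.
#' @return list with `efficiency_percent` (slope -3.3219),
#'   `ddct_fold_example` (case dCt 4 vs control 6), and `recovered_fold`.
#' @export
eval_qpcr_roundtrip <- function(seed = 1) {
  std <- data.frame(sample = "s", group = "standard", assay = "A",
                    replicate = 1, dilution = 10^(0:-4))
  std$ct <- 24 - 3.3219 * log10(std$dilution)
  eff <- fit_efficiency(std)

  ex <- data.frame(
    sample = rep(c("c1", "c2", "x1"), each = 2),
    group = rep(c("control", "control", "case"), each = 2),
    assay = rep(c("T", "R"), 3), replicate = 1,
    ct = c(26, 20, 26, 20, 24, 20), dilution = NA_real_,
    stringsAsFactors = FALSE
  )
  fold_example <- ddct(ex, "T", "R")
  fold_case <- fold_example$fold[fold_example$group == "case"]

  cfg <- sim_config(seed = seed, qpcr_noise_sd = 0.2, qpcr_n_per_group = 10)
  tab <- simulate_qpcr(cfg, c(TGT = 4))
  rel <- ddct(tab, "TGT", "HK")
  list(
    efficiency_percent = eff$efficiency_percent,
    ddct_fold_example = fold_case,
    recovered_fold = mean(rel$fold[rel$group == "case"])
  )
}

#' Storey pi0 on uniform p-values
#'
#' @param n number of uniform draws (default 10000).
#' @param seed generator seed.
#' @return the pi0 estimate.
#' @export
eval_pi0_uniform <- function(n = 10000, seed = 1) {
  with_seed(seed, storey_qvalue(stats::runif(n))$model$pi0)
}
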