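test_that("miRNA generator is deterministic and respects the planted design", {
  cfg <- sim_config(seed = 1)
  a <- simulate_mirna_matrix(cfg)
  b <- simulate_mirna_matrix(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$de_features, b$truth$de_features)

  # no planted effect: truth empty, group means differ only by noise
  cfg0 <- sim_config(seed = 1, n_de = 0, batch_sd = 0)
  m0 <- simulate_mirna_matrix(cfg0)
  expect_equal(nrow(m0$truth$de_features), 0)
  grp <- m0$matrix$samples$group
  diffs <- rowMeans(m0$matrix$values[, grp == "case"]) -
    rowMeans(m0$matrix$values[, grp == "control"])
  expect_lt(max(abs(diffs)), 5 * cfg0$noise_sd * sqrt(2 / cfg0$n_samples_per_group))

  # law of large numbers on the planted shift
  cfg7 <- sim_config(seed = 7, n_de = 20, effect_size = 1, noise_sd = 0.3)
  m7 <- simulate_mirna_matrix(cfg7)
  tr <- m7$truth$de_features
  grp <- m7$matrix$samples$group
  v <- m7$matrix$values[tr$feature, ]
  shift <- mean((rowMeans(v[, grp == "case"]) - rowMeans(v[, grp == "control"])) *
                  sign(tr$effect))
  expect_gt(shift, 0.8)
  expect_lt(shift, 1.2)

  expect_error(sim_config(seed = 1, n_de = 500), "invalid config")
  expect_error(sim_config(n_de = 5), "seed")
})

test_that("regulated transcriptome plants de-repressed targets and a consistent site table", {
  cfg <- sim_config(seed = 2, n_de = 10, de_direction = "down",
                    targets_per_mirna = 60, n_genes = 4000)
  mir <- simulate_mirna_matrix(cfg)
  tx <- simulate_regulated_transcriptome(cfg, mir$truth)

  # planted miRNA down (-1) with suppression 1: targets shift ~ +1
  grp <- tx$matrix$samples$group
  tg <- tx$truth$regulon$gene
  v <- tx$matrix$values[tg, ]
  shift <- mean(rowMeans(v[, grp == "case"]) - rowMeans(v[, grp == "control"]))
  expect_gt(shift, 0.85)
  expect_lt(shift, 1.15)

  # every planted edge appears in both tables
  edge_key <- paste(tx$truth$regulon$mirna, tx$truth$regulon$gene)
  expect_true(all(edge_key %in% paste(tx$sites$mirna, tx$sites$gene)))
  inter_val <- tx$interactions[tx$interactions$evidence == "validated", ]
  expect_true(all(edge_key %in% paste(inter_val$mirna, inter_val$gene)))
  expect_true(all(nchar(tx$sites$motif) == 7))
  expect_true(all(tx$truth$regulon$gene %in% rownames(tx$matrix$values)))

  # suppression 0: target genes indistinguishable from background
  cfg0 <- sim_config(seed = 2, n_de = 10, de_direction = "down",
                     suppression = 0, n_de_genes = 0)
  tx0 <- simulate_regulated_transcriptome(cfg0, mir$truth)
  tg0 <- tx0$truth$regulon$gene
  grp0 <- tx0$matrix$samples$group
  d0 <- rowMeans(tx0$matrix$values[, grp0 == "case"]) -
    rowMeans(tx0$matrix$values[, grp0 == "control"])
  expect_gt(t.test(d0[tg0], d0[setdiff(names(d0), tg0)])$p.value, 0.01)

  # empty regulon errors unless explicitly allowed
  cfg_up <- sim_config(seed = 3, n_de = 5, de_direction = "up")
  up <- simulate_mirna_matrix(cfg_up)
  expect_error(simulate_regulated_transcriptome(cfg_up, up$truth), "empty regulon")
  expect_silent(simulate_regulated_transcriptome(cfg_up, up$truth,
                                                 allow_empty_regulon = TRUE))
})

test_that("single-cell generator plants programs at the requested frequencies", {
  cfg <- sim_config(seed = 4, n_donors = 4, cells_per_donor = 400,
                    n_genes_sc = 600)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(
    SummarizedExperiment::assay(a$sce, "counts"),
    SummarizedExperiment::assay(b$sce, "counts")
  )

  # realized per-donor Tc17 fraction within the binomial 99% interval of 0.04
  f4 <- cfg$program_frequencies$case["Tc17"]
  expect_equal(unname(f4), 0.04)
  band <- qbinom(c(0.005, 0.995), 400, 0.04) / 400
  case_fr <- a$truth$donor_frequencies$Tc17[a$truth$donor_frequencies$group == "case"]
  expect_true(all(case_fr >= band[1] & case_fr <= band[2]))

  # zero frequencies: every label is "none"
  cfg0 <- sim_config(seed = 4, n_donors = 2, cells_per_donor = 50,
                     n_genes_sc = 600,
                     program_frequencies = list(
                       control = c(Tc17 = 0, Treg = 0),
                       case = c(Tc17 = 0, Treg = 0)
                     ))
  z <- simulate_single_cell(cfg0)
  expect_true(all(z$truth$cell_labels == "none"))

  # signature gene outside the universe is an error
  cfg_bad <- sim_config(seed = 4, n_donors = 2, cells_per_donor = 50,
                        n_genes_sc = 600,
                        gene_universe = c("CD3G", "CD8A", "CD8B", "RORC",
                                          sprintf("G%05d", 1:100)),
                        signatures = list(Tc17 = c("RORC", "NOT_A_GENE")))
  expect_error(simulate_single_cell(cfg_bad), "absent from gene universe")

  # truth ids exist in the emitted data
  expect_true(all(names(a$truth$cell_labels) %in% colnames(a$sce)))
  expect_true(all(a$truth$donor_frequencies$Tc17 >= 0 &
                    a$truth$donor_frequencies$Tc17 <= 1))
})

test_that("qPCR generator plants folds, standards, and a stable housekeeper", {
  cfg <- sim_config(seed = 5)
  tab <- simulate_qpcr(cfg, c(A = 4, B = 1))
  expect_identical(tab, simulate_qpcr(cfg, c(A = 4, B = 1)))
  expect_error(simulate_qpcr(cfg, c(A = -1)), "> 0")
  expect_error(simulate_qpcr(cfg, c(4)), "named")

  # fold 1 for an assay: expected ddCt ~ 0
  relB <- ddct(tab, "B", "HK")
  expect_lt(abs(mean(relB$ddct[relB$group == "case"])), 0.3)

  # default slope -3.3219 recovers ~100% efficiency
  eff <- fit_efficiency(tab, "A")
  expect_equal(eff$efficiency_percent, 100, tolerance = 1e-3)
  expect_true(eff$pass)

  # planted fold 4 recovered within the generator's Monte-Carlo band
  relA <- ddct(tab, "A", "HK")
  mean_fold <- mean(relA$fold[relA$group == "case"])
  expect_gt(mean_fold, 3.2)
  expect_lt(mean_fold, 4.8)
})

test_that("fixture writers round-trip every format", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, n_features = 30, n_samples_per_group = 3)
  m <- simulate_mirna_matrix(cfg)$matrix
  p <- file.path(dir, "expr.tsv")
  write_expression_tsv(m, p)
  m2 <- read_expression_tsv(p)
  expect_equal(m2$values, m$values)
  expect_equal(m2$samples$group, m$samples$group)

  # the shipped signature fixture is the default signature list
  shipped <- read_gmt(system.file("extdata", "program_signatures.gmt",
                                  package = "autoimmir"))
  expect_equal(shipped$Treg, default_signatures()$Treg)
  expect_equal(shipped$Tc17, default_signatures()$Tc17)

  sets <- list(alpha = c("a", "b", "c"), beta = c("d", "e"))
  gp <- file.path(dir, "sets.gmt")
  write_gmt(sets, gp)
  expect_equal(read_gmt(gp)[["alpha"]], sets$alpha)

  cfg_sc <- sim_config(seed = 6, n_donors = 2, cells_per_donor = 20,
                       n_genes_sc = 200)
  sce <- simulate_single_cell(cfg_sc)$sce
  md <- file.path(dir, "mtx")
  write_mtx_dir(sce, md)
  sce2 <- read_mtx_dir(md)
  expect_equal(
    as.matrix(SummarizedExperiment::assay(sce2, "counts")),
    as.matrix(SummarizedExperiment::assay(sce, "counts"))
  )
  expect_equal(SummarizedExperiment::colData(sce2)$donor,
               as.character(SummarizedExperiment::colData(sce)$donor))
})
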