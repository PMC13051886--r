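test_that("AUC recovery-curve scores match brute-force integration", {
  # deterministic construction: cell 1 carries the signature at the very top
  n_genes <- 20
  counts <- matrix(0, n_genes, 3,
                   dimnames = list(sprintf("g%02d", 1:n_genes), c("a", "b", "c")))
  sig <- c("g01", "g02")
  counts[c("g01", "g02"), "a"] <- c(50, 40)
  counts[, "b"] <- seq_len(n_genes)                # signature at ranks 19, 20
  counts[c("g01", "g03"), "c"] <- c(9, 10)         # signature at ranks 2 and >M
  sce <- tiny_sce(counts)
  sc <- aucell_score(sce, sig, top_fraction = 0.25, seed = 1)
  expect_equal(sc$auc[1], 1)                       # all signature genes on top
  expect_equal(sc$auc[2], 0)                       # none inside the top fraction

  # worked instance: n_genes = 20, top_fraction 0.25, signature ranks {1, 3}
  counts2 <- matrix(0, n_genes, 1,
                    dimnames = list(sprintf("g%02d", 1:n_genes), "x"))
  counts2[, 1] <- seq(n_genes, 1)                  # g01 highest ... g20 lowest
  sce2 <- tiny_sce(counts2)
  sc2 <- aucell_score(sce2, c("g01", "g03"), top_fraction = 0.25, seed = 1)
  expect_equal(sc2$auc, aucell_oracle(c(1, 3), n_genes, 0.25, 2),
               tolerance = 1e-12)

  # randomized instances with <= 30 genes against the step-curve oracle
  for (s in 1:15) {
    set.seed(s)
    ng <- sample(10:30, 1)
    x <- sample(1000, ng)                          # distinct counts: no ties
    cm <- matrix(x, ng, 1, dimnames = list(sprintf("g%02d", 1:ng), "c"))
    sig_genes <- sample(rownames(cm), sample(2:5, 1))
    tf <- runif(1, 0.1, 0.5)
    got <- aucell_score(tiny_sce(cm), sig_genes, top_fraction = tf, seed = s)
    pos <- rank(-x)[match(sig_genes, rownames(cm))]
    expect_equal(got$auc, aucell_oracle(pos, ng, tf, length(sig_genes)),
                 tolerance = 1e-12)
  }

  expect_identical(aucell_score(sce, sig, seed = 3),
                   aucell_score(sce, sig, seed = 3))
  expect_error(aucell_score(sce, "absent"), "no signature gene")
  expect_error(aucell_score(sce, sig, top_fraction = 0.7), "top_fraction")
})

test_that("classification thresholds act as documented", {
  sc <- data.frame(cell = c("a", "b", "c"), auc = c(0, 0.17, 0.9))
  class(sc) <- c("SignatureScoreTable", "data.frame")
  expect_equal(unname(classify_cells(sc, 0)), c(TRUE, TRUE, TRUE))
  expect_equal(unname(classify_cells(sc, 0.17)), c(FALSE, TRUE, TRUE))
  expect_equal(unname(classify_cells(sc, 1)), c(FALSE, FALSE, FALSE))
  expect_error(classify_cells(sc, 1.5), "threshold")
  expect_equal(default_auc_thresholds(), c(Treg = 0.17, Tc17 = 0.22))
})

test_that("tree-ensemble TF activity finds the generating regulator", {
  set.seed(8)
  n_genes <- 120
  genes <- sprintf("g%03d", seq_len(n_genes))
  net <- data.frame(
    tf = rep(c("A", "B", "C"), each = 20),
    target = c(genes[1:20], genes[41:60], genes[81:100]),
    weight = 1
  )
  # cells whose expression equals TF A's membership column (targets high)
  expr <- matrix(0.1, n_genes, 4, dimnames = list(genes, sprintf("c%d", 1:4)))
  expr[1:20, ] <- 5
  sce <- tiny_sce(round(2^expr))
  sce <- normalize_log(sce)
  hits <- 0
  for (s in 1:5) {
    act <- tf_activity_mdt(sce, net, n_trees = 50, seed = s)
    hits <- hits + all(apply(act$activity, 2, which.max) == 1)
  }
  expect_gte(hits, 4)

  act <- tf_activity_mdt(sce, net, n_trees = 50, seed = 1)
  expect_equal(unname(colSums(act$activity)), rep(1, 4), tolerance = 1e-12)
  expect_identical(act$activity,
                   tf_activity_mdt(sce, net, n_trees = 50, seed = 1)$activity)

  # constant expression: uniform activities with the degenerate flag
  flat <- tiny_sce(matrix(3, n_genes, 2, dimnames = list(genes, c("x", "y"))))
  flat <- normalize_log(flat)
  actf <- tf_activity_mdt(flat, net, n_trees = 20, seed = 1)
  expect_true(all(actf$degenerate))
  expect_equal(unname(actf$activity[, 1]), rep(1 / 3, 3))

  # gene-order permutation leaves the dominant TF unchanged
  perm <- sample(n_genes)
  actp <- tf_activity_mdt(sce[perm, ], net, n_trees = 50, seed = 1)
  expect_equal(unname(apply(actp$activity, 2, which.max)), rep(1, 4))

  expect_warning(
    tf_activity_mdt(sce, rbind(net, data.frame(tf = "D", target = genes[1:2],
                                               weight = 1)),
                    n_trees = 20, seed = 1),
    "dropped"
  )
  expect_error(tf_activity_mdt(sce, net[net$tf == "A", ], seed = 1), "2 usable")
})

test_that("donor-mean activities are compared with Welch tests per TF", {
  act <- matrix(0, 2, 8, dimnames = list(c("TF1", "TF2"), sprintf("c%d", 1:8)))
  meta <- data.frame(cell = sprintf("c%d", 1:8),
                     donor = rep(sprintf("d%d", 1:4), each = 2),
                     group = rep(c("control", "case"), each = 4))
  # TF1: identical group distributions -> t = 0, p = 1
  act["TF1", ] <- c(0.2, 0.4, 0.3, 0.5, 0.2, 0.4, 0.3, 0.5)
  # TF2: clear group difference
  act["TF2", ] <- rep(c(0.1, 0.1, 0.9, 0.9), each = 2)
  am <- structure(list(activity = act, degenerate = rep(FALSE, 8)),
                  class = "ActivityMatrix")
  res <- donor_mean_activity(am, meta)
  expect_equal(dim(res$donor_means), c(2, 4))
  expect_equal(res$tests$p[res$tests$tf == "TF1"], 1)
  expect_equal(res$tests$t[res$tests$tf == "TF1"], 0)
  expect_lt(res$tests$p[res$tests$tf == "TF2"], 0.01)
  # averaging is invariant to cell order
  perm <- sample(8)
  res2 <- donor_mean_activity(
    structure(list(activity = act[, perm]), class = "ActivityMatrix"),
    meta[perm, ]
  )
  expect_equal(res2$donor_means[, colnames(res$donor_means)], res$donor_means)
})

test_that("signature markers of planted Tc17 cells recover an IL-17-like set", {
  cfg <- sim_config(seed = 51, n_donors = 2, cells_per_donor = 150,
                    n_genes_sc = 1000,
                    program_frequencies = list(control = c(Tc17 = 0.1, Treg = 0),
                                               case = c(Tc17 = 0.1, Treg = 0)))
  sim <- simulate_single_cell(cfg)
  sce <- normalize_log(sim$sce)
  truth <- sim$truth$cell_labels[colnames(sce)]
  labels <- truth == "Tc17"
  pathway <- list(il17_like = default_signatures()$Tc17)
  res <- verify_signature_markers(sce, labels, pathway, top_n = 100,
                                  min_size = 5)
  expect_true("il17_like" %in% res$enriched$set)

  # shuffled labels lose the enrichment in the clear majority of permutations
  set.seed(1)
  null_hits <- sum(vapply(1:5, function(i) {
    res0 <- verify_signature_markers(sce, sample(labels), pathway, top_n = 100,
                                     min_size = 5)
    "il17_like" %in% res0$enriched$set
  }, logical(1)))
  expect_lte(null_hits, 1)
  expect_error(verify_signature_markers(sce, rep(FALSE, ncol(sce)), pathway),
               "< 5 cells")
})

test_that("frequency comparison recovers planted group differences", {
  mk_meta <- function(fracs, cells = 1000) {
    donors <- sprintf("d%02d", seq_along(fracs))
    cells_df <- do.call(rbind, lapply(seq_along(fracs), function(i) {
      data.frame(cell = sprintf("%s_c%04d", donors[i], 1:cells),
                 donor = donors[i],
                 group = if (i <= length(fracs) / 2) "control" else "case")
    }))
    pos <- unlist(lapply(seq_along(fracs), function(i) {
      c(rep(TRUE, round(fracs[i] * cells)),
        rep(FALSE, cells - round(fracs[i] * cells)))
    }))
    list(labels = setNames(pos, cells_df$cell), meta = cells_df)
  }
  # the Welch closed-form example
  f <- mk_meta(c(0.019, 0.020, 0.021, 0.039, 0.040, 0.041))
  res <- compare_frequencies(f$labels, f$meta)
  expect_lt(res$test$p, 0.001)
  expect_true(all(res$fractions$fraction >= 0 & res$fractions$fraction <= 1))

  # equal fractions in both groups: t = 0, p = 1
  f0 <- mk_meta(c(0.01, 0.03, 0.01, 0.03))
  res0 <- compare_frequencies(f0$labels, f0$meta)
  expect_equal(res0$test$t, 0)
  expect_equal(res0$test$p, 1)

  # small donors are excluded with a warning
  small <- f0
  small$meta$donor[1:5] <- "tiny"
  small$labels <- small$labels[small$meta$cell %in% small$meta$cell]
  expect_warning(compare_frequencies(small$labels, small$meta), "excluding")
})
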