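test_that("CD8 gating requires CD3G plus either CD8A or CD8B", {
  counts <- rbind(CD3G = c(1, 0, 1, 2),
                  CD8A = c(2, 5, 0, 0),
                  CD8B = c(0, 0, 1, 0),
                  OTHER = c(3, 3, 3, 3))
  sce <- tiny_sce(counts)
  gated <- gate_cd8(sce)
  expect_equal(colnames(gated), c("c001", "c003"))
  expect_equal(S4Vectors::metadata(gated)$gate$n_kept, 2)
  expect_error(gate_cd8(tiny_sce(counts[-1, , drop = FALSE])), "CD3G")
})

test_that("QC filtering flags outliers on all three metrics", {
  set.seed(1)
  n <- 60
  counts <- matrix(rpois(20 * n, 20), 20, n)
  rownames(counts) <- c(sprintf("G%02d", 1:18), "MT-1", "MT-2")
  sce <- tiny_sce(counts)
  clean <- qc_filter(sce, nmads = 3)
  expect_equal(ncol(clean), n)  # homogeneous cells: none removed

  # a cell with extreme mitochondrial load is flagged
  bad <- counts
  bad[c("MT-1", "MT-2"), 1] <- 200
  flagged <- qc_filter(tiny_sce(bad), nmads = 3)
  expect_false("c001" %in% colnames(flagged))
  expect_equal(S4Vectors::metadata(flagged)$qc$flagged_mito, 1)

  # a near-empty cell is flagged on totals/detected
  bad2 <- counts
  bad2[, 2] <- 0; bad2[1, 2] <- 1
  flagged2 <- qc_filter(tiny_sce(bad2), nmads = 3)
  expect_false("c002" %in% colnames(flagged2))

  # infinite nmads is the identity
  expect_equal(ncol(qc_filter(tiny_sce(bad), nmads = Inf)), n)
  expect_error(qc_filter(tiny_sce(counts[, 1:9]), nmads = 0.0001), "10 cells")
})

test_that("log normalization is scale-invariant per cell", {
  counts <- matrix(c(1, 2, 3, 2, 4, 6, 5, 0, 1), 3)
  sce <- normalize_log(tiny_sce(counts))
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  # doubling a cell's counts leaves its normalized profile unchanged
  expect_equal(as.numeric(lc[, 1]), as.numeric(lc[, 2]), tolerance = 1e-12)
  # zero stays zero
  expect_equal(lc[2, 3], 0)
  # equal totals: scaling is the identity
  eq <- matrix(c(3, 3, 2, 4), 2)
  lceq <- SummarizedExperiment::assay(normalize_log(tiny_sce(eq)), "logcounts")
  expect_equal(as.matrix(lceq), log2(eq + 1), ignore_attr = TRUE)
  zero <- matrix(c(1, 1, 0, 0), 2)
  expect_error(normalize_log(tiny_sce(zero)), "zero-total")
})

test_that("HVG selection finds planted high-variance genes", {
  set.seed(2)
  n <- 200
  # genes spanning a range of abundances anchor the mean-variance trend
  counts <- matrix(rpois(100 * n, seq(1, 12, length.out = 100)), 100, n)
  counts[7, ] <- rep(c(1, 25), length.out = n)   # bimodal, log-mean in range
  sce <- normalize_log(tiny_sce(counts))
  hv <- select_hvgs(sce, 10)
  expect_true("g007" %in% hv)

  # signature genes amplified in a planted subpopulation are highly variable
  cfg <- sim_config(seed = 22, n_donors = 2, cells_per_donor = 200,
                    n_genes_sc = 400,
                    program_frequencies = list(control = c(Tc17 = 0.1, Treg = 0),
                                               case = c(Tc17 = 0.1, Treg = 0)))
  ssim <- normalize_log(simulate_single_cell(cfg)$sce)
  hv_sig <- select_hvgs(ssim, 50)
  expect_gte(length(intersect(hv_sig, default_signatures()$Tc17)), 5)
  expect_setequal(select_hvgs(sce, 100), rownames(sce))
  expect_error(select_hvgs(sce, 101), "exceeds")
})

test_that("MNN-lite correction removes planted batch shifts and nothing else", {
  set.seed(3)
  base <- matrix(rpois(100 * 120, 8), 100, 120)
  rownames(base) <- sprintf("g%03d", 1:100)

  # literally identical batches: correction vectors ~ 0
  twin <- cbind(base, base)
  colnames(twin) <- sprintf("c%03d", seq_len(ncol(twin)))
  sce0 <- normalize_log(tiny_sce(twin, donor = rep(c("d1", "d2"), each = 120)))
  emb0 <- correct_batch(sce0, rownames(base), n_pcs = 10, k = 10)
  move0 <- mean(sqrt(rowSums((emb0$embedding[121:240, ] - emb0$raw[121:240, ])^2)))
  cell_scale <- mean(sqrt(rowSums(emb0$raw^2)))
  expect_lt(move0, 0.1 * cell_scale)

  # planted constant shift: centroid distance drops by >= 80%
  shifted <- base
  shifted[1:50, 61:120] <- shifted[1:50, 61:120] + 12
  sce1 <- normalize_log(tiny_sce(shifted, donor = rep(c("d1", "d2"), each = 60)))
  emb1 <- correct_batch(sce1, rownames(base), n_pcs = 10, k = 10)
  centroid_gap <- function(M) sqrt(sum((colMeans(M[1:60, ]) - colMeans(M[61:120, ]))^2))
  expect_lt(centroid_gap(emb1$embedding), 0.2 * centroid_gap(emb1$raw))

  # single batch: identity
  sce2 <- normalize_log(tiny_sce(base))
  emb2 <- correct_batch(sce2, rownames(base), n_pcs = 10, k = 10)
  expect_identical(emb2$embedding, emb2$raw)
  expect_error(correct_batch(sce1, rownames(base), k = 100), "fewer than k")
})

test_that("SNN-Louvain separates well-separated blobs and is deterministic", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(40 * 3, 0, 0.5), 40, 3),
               matrix(rnorm(40 * 3, 20, 0.5), 40, 3))
  rownames(emb) <- sprintf("c%03d", 1:80)
  cl <- snn_louvain(emb, k = 10, seed = 1, resolution = 0.25)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:40])), 1)
  expect_equal(length(unique(cl[41:80])), 1)
  expect_identical(cl, snn_louvain(emb, k = 10, seed = 1, resolution = 0.25))

  # modularity of the returned partition beats all-singletons
  expect_gt(attr(cl, "modularity"), 0)
  expect_error(snn_louvain(emb, k = 80), "k must be")
})

test_that("SNN edge weight is 1 for cells sharing all k neighbors", {
  # two probes on opposite sides of a central cluster of k cells share
  # exactly that cluster as neighbors
  k <- 4
  cluster <- matrix(rnorm(k * 2, 0, 0.05), k, 2)
  emb <- rbind(cluster, c(-1, 0), c(1, 0))
  rownames(emb) <- sprintf("c%d", 1:6)
  n <- nrow(emb)
  d <- as.matrix(dist(emb)); diag(d) <- Inf
  nn <- t(apply(d, 1, function(x) order(x)[seq_len(k)]))
  expect_setequal(nn[5, ], 1:k)
  expect_setequal(nn[6, ], 1:k)
  M <- Matrix::sparseMatrix(i = rep(1:n, each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(M)
  jac <- inter[5, 6] / (2 * k - inter[5, 6])
  expect_equal(jac, 1)
})

test_that("label transfer assigns the best-correlated reference profile", {
  set.seed(5)
  profiles <- matrix(rexp(120 * 2, 1), 120, 2,
                     dimnames = list(sprintf("g%03d", 1:120), c("T", "B")))
  counts <- cbind(round(50 * profiles[, "T"]), round(50 * profiles[, "B"]))
  colnames(counts) <- c("cellT", "cellB")
  sce <- normalize_log(tiny_sce(counts + 1))
  res <- label_transfer(sce, profiles)
  expect_equal(res$label, c("T", "B"))
  expect_gt(min(res$score), 0.8)

  # gene-order permutation leaves assignments unchanged
  perm <- sample(nrow(profiles))
  res2 <- label_transfer(sce, profiles[perm, ])
  expect_equal(res2$label, res$label)
  expect_equal(res2$score, res$score, tolerance = 1e-12)
  expect_error(label_transfer(sce, profiles[1:10, ]), "overlap")
})

test_that("marker AUC matches exhaustive pair counting", {
  set.seed(6)
  labels <- rep(c("A", "B", "C"), times = c(8, 12, 15))
  counts <- matrix(rpois(10 * length(labels), 5), 10)
  counts[1, labels == "A"] <- 50      # exclusive marker
  counts[2, ] <- 7                    # constant gene
  sce <- tiny_sce(counts)
  sm <- score_markers(sce, labels)
  expect_equal(unname(sm$auc["g001", "A"]), 1)
  expect_equal(unname(sm$auc["g002", ]), rep(0.5, 3), ignore_attr = TRUE)

  # oracle: brute-force pair counting on every gene, A vs B
  x <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  for (g in 1:10) {
    ab <- auc_pairs_oracle(x[g, labels == "A"], x[g, labels == "B"])
    ac <- auc_pairs_oracle(x[g, labels == "A"], x[g, labels == "C"])
    expect_equal(unname(sm$auc[g, "A"]), mean(c(ab, ac)), tolerance = 1e-12)
  }
  expect_error(score_markers(sce, rep("A", length(labels))), "2 clusters")
})

test_that("pseudobulk aggregation conserves counts and validates donors", {
  counts <- matrix(c(1, 3, 2, 4, 5, 6), 2, 3)
  sce <- tiny_sce(counts, donor = c("d1", "d1", "d2"),
                  group = c("control", "control", "case"))
  pb <- pseudobulk(sce, min_cells = 1)
  expect_equal(unname(pb$counts[, "d1"]), c(3, 7))
  expect_equal(sum(pb$counts), sum(counts))
  expect_equal(pb$donors$group, c("control", "case"))

  expect_warning(pb2 <- pseudobulk(sce, min_cells = 2), "dropping")
  expect_equal(colnames(pb2$counts), "d1")

  bad <- tiny_sce(counts, donor = c("d1", "d1", "d1"),
                  group = c("control", "case", "case"))
  expect_error(pseudobulk(bad), "mixed group")
})

test_that("TMM factors behave canonically and match the edgeR oracle", {
  set.seed(7)
  counts <- matrix(rnbinom(400 * 6, mu = rlnorm(400, 3, 1), size = 5), 400, 6)
  rownames(counts) <- sprintf("g%03d", 1:400)
  colnames(counts) <- sprintf("d%d", 1:6)
  pb <- structure(list(counts = counts), class = "Pseudobulk")

  same <- structure(list(counts = counts[, c(1, 1, 1)]), class = "Pseudobulk")
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)

  doubled <- structure(list(counts = cbind(counts[, 1:3], 2 * counts[, 1])),
                       class = "Pseudobulk")
  f2 <- tmm_factors(doubled)
  expect_equal(unname(f2[4] / f2[1]), 1, tolerance = 1e-6)

  f <- tmm_factors(pb)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  f_edger <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_equal(unname(f), f_edger, tolerance = 0.02)

  zero <- structure(list(counts = cbind(counts[, 1], 0)), class = "Pseudobulk")
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("pseudobulk NB-QL DE is cell-order invariant and finds planted folds", {
  cfg <- sim_config(seed = 41, n_donors = 4, cells_per_donor = 60,
                    n_genes_sc = 500,
                    program_frequencies = list(control = c(Tc17 = 0, Treg = 0),
                                               case = c(Tc17 = 0, Treg = 0)))
  sim <- simulate_single_cell(cfg)
  sce <- sim$sce
  # plant a 4-fold group effect in 10 genes at the count level
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  case_cells <- SummarizedExperiment::colData(sce)$group == "case"
  idx <- 101:110
  counts[idx, case_cells] <- counts[idx, case_cells] * 4L
  sce2 <- tiny_sce(counts,
                   donor = as.character(SummarizedExperiment::colData(sce)$donor),
                   group = as.character(SummarizedExperiment::colData(sce)$group))
  pb <- pseudobulk(sce2)
  r <- nb_ql_test(pb)
  planted <- rownames(counts)[idx]
  found <- r$table$feature[r$table$q < 0.1 & r$table$log2FC > 1]
  expect_gte(length(intersect(found, planted)), 8)

  # permuting cells leaves the result identical
  perm <- sample(ncol(counts))
  pbp <- pseudobulk(sce2[, perm])
  rp <- nb_ql_test(pbp)
  expect_equal(rp$table[order(rp$table$feature), ],
               r$table[order(r$table$feature), ], ignore_attr = TRUE)

  solo <- pb
  solo$counts <- solo$counts[, c(1, 2, 5), drop = FALSE]
  solo$donors <- solo$donors[c(1, 2, 5), ]
  expect_error(nb_ql_test(solo), "2 donors")
})
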