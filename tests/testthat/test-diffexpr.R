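test_that("top-expression filter keeps the right features with deterministic ties", {
  m <- tiny_matrix(matrix(c(10, 9, 8, 7, 6), 5, 4, byrow = FALSE) +
                     matrix(0, 5, 4))
  m$values[] <- rep(c(10, 9, 8, 7, 6), 4)
  expect_identical(filter_top_expressed(m, 5)$values, m$values)
  expect_equal(rownames(filter_top_expressed(m, 2)$values), c("f01", "f02"))
  # ties broken lexicographically
  mt <- tiny_matrix(matrix(5, 3, 2, dimnames = list(c("b", "a", "c"), NULL)))
  expect_setequal(rownames(filter_top_expressed(mt, 2)$values), c("a", "b"))
  expect_error(filter_top_expressed(m, 0), "out of range")
  expect_error(filter_top_expressed(m, 6), "out of range")
})

test_that("quantile normalization equalizes sorted column vectors", {
  m <- tiny_matrix(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  m2 <- random_matrix(1, n_features = 40, n_per_group = 3)
  qn2 <- quantile_normalize(m2)
  sorted <- apply(qn2$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  same <- tiny_matrix(matrix(rep(c(3, 1, 2), 4), 3, 4))
  expect_equal(quantile_normalize(same)$values, same$values)
})

test_that("probe averaging and intensity filtering follow their definitions", {
  m <- tiny_matrix(rbind(p1 = c(2, 4), p2 = c(4, 6), p3 = c(1, 1)))
  mapping <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  avg <- average_duplicate_features(m, mapping)
  expect_equal(unname(avg$values["gA", ]), c(3, 5))
  expect_equal(nrow(avg$values), 2)
  expect_error(average_duplicate_features(m, c(p1 = "gA")), "cover")

  one2one <- average_duplicate_features(m, c(p1 = "x1", p2 = "x2", p3 = "x3"))
  expect_equal(sort(rownames(one2one$values)), c("x1", "x2", "x3"))

  mi <- tiny_matrix(rbind(lo = c(5.9, 5.9), edge = c(6, 6), hi = c(7, 7)))
  kept <- filter_low_intensity(mi, 6)
  expect_setequal(rownames(kept$values), c("edge", "hi"))
  expect_identical(filter_low_intensity(mi, -Inf)$values, mi$values)
  expect_error(filter_low_intensity(mi, 100), "below")
})

test_that("surrogate variables recover planted batches and stay null-calibrated", {
  # a planted batch shift affecting half the features is found, |r| > 0.8
  set.seed(10)
  n <- 12
  v <- matrix(rnorm(100 * n, 8, 0.3), 100, n)
  batch <- rep(c(0, 1), 6)  # balanced across groups
  v[1:50, ] <- v[1:50, ] + 1.0 * matrix(batch, 50, n, byrow = TRUE)
  m <- tiny_matrix(v, rep(c("control", "case"), each = 6))
  sv <- estimate_surrogate_variables(m, seed = 1)
  expect_gte(ncol(sv), 1)
  expect_gt(abs(cor(sv[, 1], batch)), 0.8)

  # null matrices: auto picks zero components in >= 90% of runs
  n_zero <- sum(vapply(1:20, function(s) {
    set.seed(100 + s)
    mm <- tiny_matrix(matrix(rnorm(60 * 8, 8, 0.4), 60, 8),
                      rep(c("control", "case"), each = 4))
    ncol(estimate_surrogate_variables(mm, seed = s)) == 0
  }, logical(1)))
  expect_gte(n_zero, 18)

  # n_sv = 0: empty matrix, downstream DE unchanged
  sv0 <- estimate_surrogate_variables(m, n_sv = 0)
  expect_equal(dim(sv0), c(12, 0))
  expect_equal(moderated_t_test(m, covariates = sv0)$table,
               moderated_t_test(m)$table)
  expect_error(estimate_surrogate_variables(m, n_sv = 10), "n_sv")
})

test_that("moderated t with d0 = 0 equals the classical pooled t-test", {
  m <- random_matrix(2, n_features = 60, n_per_group = 4, effect = 1)
  r <- moderated_t_test(m, params = list(d0 = 0, s0_sq = 1))
  grp <- m$samples$group
  for (i in seq_len(nrow(m$values))) {
    ct <- t.test(m$values[i, grp == "case"], m$values[i, grp == "control"],
                 var.equal = TRUE)
    expect_equal(r$table$t[i], unname(ct$statistic), tolerance = 1e-9)
    expect_equal(r$table$p[i], ct$p.value, tolerance = 1e-9)
  }
  # worked example: (1,2,3) control vs (4,5,6) case
  m2 <- tiny_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1),
                    rep(c("control", "case"), each = 3))
  r2 <- moderated_t_test(m2, params = list(d0 = 0, s0_sq = 1))
  expect_equal(r2$table$t, 3.674235, tolerance = 1e-6)
  expect_equal(r2$table$p, 0.02131164, tolerance = 1e-6)
})

test_that("variance shrinkage brackets and matches the limma oracle", {
  m <- random_matrix(3, n_features = 300, n_per_group = 5, effect = 0.8)
  r <- moderated_t_test(m)
  s2 <- r$params$s2
  s_tilde2 <- (r$params$d0 * r$params$s0_sq + r$params$dg * s2) /
    (r$params$d0 + r$params$dg)
  expect_true(all(s_tilde2 >= pmin(s2, r$params$s0_sq) - 1e-12))
  expect_true(all(s_tilde2 <= pmax(s2, r$params$s0_sq) + 1e-12))

  # d0 = Inf pools every variance to s0^2
  rinf <- moderated_t_test(m, params = list(d0 = Inf, s0_sq = 0.3))
  expect_equal(unname(rinf$table$t),
               unname(r$table$log2FC / sqrt(0.3 * 2 / 5)), tolerance = 1e-6)

  # independent oracle: limma's empirical-Bayes machinery on the same data
  design <- cbind(1, as.numeric(m$samples$group == "case"))
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(unname(r$params$d0), unname(fit$df.prior), tolerance = 1e-4)
  expect_equal(unname(r$params$s0_sq), unname(fit$s2.prior), tolerance = 1e-4)
  expect_equal(unname(r$table$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(r$table$p), unname(fit$p.value[, 2]), tolerance = 1e-6)

  # singular designs are refused with the offending columns named
  expect_error(
    moderated_t_test(m, covariates = cbind(dup = as.numeric(m$samples$group == "case"))),
    "collinear"
  )
})

test_that("array quality weights down-weight noisy arrays", {
  set.seed(4)
  v <- matrix(rnorm(80 * 8, 8, 0.3), 80, 8)
  v[, 1] <- v[, 1] + rnorm(80, 0, 2)  # one bad array
  m <- tiny_matrix(v, rep(c("control", "case"), each = 4))
  w <- array_quality_weights(m)
  expect_equal(mean(w), 1)
  expect_equal(unname(which.min(w)), 1L)
  rw <- moderated_t_test(m, weights = w)
  expect_s3_class(rw, "DEResult")
})

test_that("classical MDS reproduces exact low-dimensional configurations", {
  # colinear configuration: 1-D coordinates reproduce pairwise distances
  m <- tiny_matrix(matrix(c(0, 0, 1, 1, 3, 3), 2, 3),
                   c("control", "control", "case"))
  md <- classical_mds(m, dims = 1, top_features = 2)
  expect_lt(max(abs(as.matrix(dist(md$coords)) - md$dist)), 1e-9)

  # identical samples collapse to the origin
  same <- tiny_matrix(matrix(5, 10, 4))
  md0 <- classical_mds(same, dims = 2, top_features = 5)
  expect_lt(max(abs(md0$coords)), 1e-9)

  expect_true(isSymmetric(md$dist))
  expect_true(all(diag(md$dist) == 0))
  expect_error(classical_mds(m, dims = 3), "dims")
})

test_that("DE calling applies strict thresholds and partitions by sign", {
  tab <- data.frame(
    feature = c("a", "b", "c", "d"),
    log2FC = c(0.7, -0.9, 0.7, 0.5),
    t = c(3, -4, 3, 2), p = c(0.01, 0.001, 0.02, 0.03),
    q = c(0.05, 0.01, 0.1, 0.05),
    adj_p = c(0.05, 0.01, 0.1, 0.05),
    mean_expr = 8
  )
  r <- structure(list(table = tab), class = "DEResult")
  hits <- call_de(r, q_max = 0.1, min_abs_fc = 1.5)
  expect_equal(hits$up, "a")       # 0.7 > log2(1.5); q 0.05 < 0.1
  expect_equal(hits$down, "b")
  expect_false("c" %in% hits$all)  # q = 0.1 exactly: strict <
  expect_false("d" %in% hits$all)  # 0.5 < log2(1.5)
  empty <- call_de(r, q_max = 0.001, min_abs_fc = 1.5)
  expect_length(empty$all, 0)
})
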