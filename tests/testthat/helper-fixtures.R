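# shared fixture builders; everything is generated in code, no stored data

# tiny two-group matrix with hand-set values
tiny_matrix <- function(values, groups = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  }
  n <- ncol(values)
  if (is.null(groups)) groups <- rep(c("control", "case"), length.out = n)
  samples <- data.frame(
    sample = sprintf("s%02d", seq_len(n)),
    group = groups,
    stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample
  expression_matrix(values, samples)
}

# random two-group matrix
random_matrix <- function(seed, n_features = 50, n_per_group = 5, effect = 0,
                          noise_sd = 0.5) {
  set.seed(seed)
  n <- 2 * n_per_group
  v <- matrix(rnorm(n_features * n, 8, noise_sd), n_features, n)
  if (effect != 0) v[1:5, (n_per_group + 1):n] <- v[1:5, (n_per_group + 1):n] + effect
  tiny_matrix(v, rep(c("control", "case"), each = n_per_group))
}

# minimal SingleCellExperiment from a dense count matrix
tiny_sce <- function(counts, donor = NULL, group = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  n <- ncol(counts)
  if (is.null(donor)) donor <- rep("D1", n)
  if (is.null(group)) group <- rep("control", n)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell = colnames(counts), donor = donor, group = group,
      row.names = colnames(counts)
    ),
    rowData = S4Vectors::DataFrame(
      mito = startsWith(rownames(counts), "MT-"), row.names = rownames(counts)
    )
  )
}

# independent oracle: hypergeometric upper tail by combinatorial enumeration
hyper_tail_oracle <- function(overlap, K, N, n) {
  ks <- overlap:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# independent oracle: two-sided Fisher p for a 2x2 table by enumerating all
# tables with the observed margins and summing those no more likely
fisher_oracle <- function(a, b, c, d) {
  K <- a + b
  n <- a + c
  N <- a + b + c + d
  as <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, as) * choose(N - K, n - as) / choose(N, n)
  p_obs <- probs[as == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: GSEA running sum evaluated position by position
gsea_es_oracle <- function(stats, members, p_w = 1) {
  o <- order(-stats, names(stats))
  ranked <- names(stats)[o]
  absw <- abs(stats[o])^p_w
  hit <- ranked %in% members
  NR <- sum(absw[hit])
  N <- length(ranked)
  walk <- cumsum(ifelse(hit, if (NR > 0) absw / NR else 1 / sum(hit),
                        -1 / (N - sum(hit))))
  if (max(walk) >= -min(walk)) max(walk) else min(walk)
}

# independent oracle: AUC recovery curve integrated step by step
aucell_oracle <- function(ranking_positions, n_genes, top_fraction, n_sig) {
  M <- ceiling(top_fraction * n_genes)
  hits_at <- vapply(seq_len(M), function(x) sum(ranking_positions <= x), numeric(1))
  max_at <- pmin(seq_len(M), n_sig)
  sum(hits_at) / sum(max_at)
}

# independent oracle: AUC by exhaustive pair counting
auc_pairs_oracle <- function(xa, xb) {
  wins <- 0
  for (i in seq_along(xa)) {
    for (j in seq_along(xb)) {
      wins <- wins + (xa[i] > xb[j]) + 0.5 * (xa[i] == xb[j])
    }
  }
  wins / (length(xa) * length(xb))
}
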