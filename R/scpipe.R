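# single-cell stage: gating, QC, normalization, HVGs, batch correction,
# SNN/Louvain clustering, label transfer, marker AUC scoring

.counts <- function(sce) SummarizedExperiment::assay(sce, "counts")
.logcounts <- function(sce) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    stop("log layer missing; run normalize_log() first")
  }
  SummarizedExperiment::assay(sce, "logcounts")
}

#' Gate CD8 T cells on lineage-marker expression
#'
#' Keeps cells with detected CD3G (count > 0) and at least one of CD8A or
#' CD8B detected. "Expression" is operationalized as a nonzero count since
#' droplet data carry no natural cutoff.
#'
#' @param sce a `SingleCellExperiment` with a counts assay.
#' @return the gated `SingleCellExperiment`; the number of cells in/out is
#'   stored in `metadata(sce)$gate`.
#' @export
gate_cd8 <- function(sce) {
  counts <- .counts(sce)
  need <- c("CD3G", "CD8A", "CD8B")
  if (!all(need %in% rownames(counts))) {
    stop("lineage genes absent: ", paste(setdiff(need, rownames(counts)), collapse = ", "))
  }
  keep <- counts["CD3G", ] > 0 & (counts["CD8A", ] > 0 | counts["CD8B", ] > 0)
  out <- sce[, keep]
  S4Vectors::metadata(out)$gate <- list(n_in = ncol(sce), n_kept = sum(keep))
  out
}

#' Median-absolute-deviation outlier filter for cell quality
#'
#' Flags cells with `log1p(total counts)` or `log1p(detected genes)` below
#' `median - nmads * MAD`, or mitochondrial percentage above
#' `median + nmads * MAD`, and removes them.
#'
#' @param sce a `SingleCellExperiment`; `rowData(sce)$mito` marks
#'   mitochondrial genes.
#' @param nmads MAD multiplier (default 3, the customary value).
#' @return filtered `SingleCellExperiment`; per-metric flag counts in
#'   `metadata(sce)$qc`.
#' @export
qc_filter <- function(sce, nmads = 3) {
  counts <- .counts(sce)
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito)) stop("rowData(sce)$mito is required")
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_pct <- 100 * Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)

  low_tail <- function(x) {
    if (!is.finite(nmads)) return(rep(FALSE, length(x)))
    x < stats::median(x) - nmads * stats::mad(x)
  }
  high_tail <- function(x) {
    if (!is.finite(nmads)) return(rep(FALSE, length(x)))
    x > stats::median(x) + nmads * stats::mad(x)
  }
  flag_total <- low_tail(log1p(total))
  flag_detected <- low_tail(log1p(detected))
  flag_mito <- high_tail(mito_pct)
  drop <- flag_total | flag_detected | flag_mito
  if (ncol(sce) - sum(drop) < 10) stop("fewer than 10 cells survive QC")
  out <- sce[, !drop]
  S4Vectors::metadata(out)$qc <- list(
    n_in = ncol(sce), n_kept = sum(!drop),
    flagged_total = sum(flag_total), flagged_detected = sum(flag_detected),
    flagged_mito = sum(flag_mito)
  )
  out
}

#' Library-size normalization and log2 transform
#'
#' Counts are scaled so every cell's total equals the median library size,
#' then transformed as `log2(x + 1)` into a `logcounts` assay.
#'
#' @param sce a `SingleCellExperiment` with positive cell totals.
#' @return `sce` with an added sparse `logcounts` assay.
#' @export
normalize_log <- function(sce) {
  counts <- .counts(sce)
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("zero-total cells present; run qc_filter() first")
  sf <- total / stats::median(total)
  lc <- .as_csparse(counts)
  lc@x <- lc@x / rep.int(sf, diff(lc@p))
  lc@x <- log2(lc@x + 1)
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  sce
}

#' Select highly variable genes from a mean-variance trend
#'
#' A loess trend of per-gene variance on per-gene mean of the log layer;
#' genes are ranked by residual variance (observed minus trend), ties broken
#' by gene id.
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param n number of genes to return (default 5000).
#' @param span loess span.
#' @return character vector of the top `n` gene ids.
#' @export
select_hvgs <- function(sce, n = 5000, span = 0.5) {
  lc <- .logcounts(sce)
  if (n > nrow(lc)) stop("n exceeds the number of genes")
  nc <- ncol(lc)
  mu <- Matrix::rowMeans(lc)
  sq <- lc
  sq@x <- sq@x^2
  v <- (Matrix::rowSums(sq) - nc * mu^2) / (nc - 1)
  fit <- stats::loess(v ~ mu, span = span, degree = 2,
                      family = "symmetric")
  resid <- v - stats::predict(fit, mu)
  o <- order(-resid, rownames(lc))
  rownames(lc)[o[seq_len(n)]]
}

#' Batch correction by mutual nearest neighbors in PCA space
#'
#' A simplified MNN scheme: PCA on the HVG log layer, then for each batch
#' after the first, mutual k-nearest-neighbor cell pairs against the
#' already-integrated cells define pair difference vectors; each incoming
#' cell is shifted by a Gaussian-kernel-smoothed average of those vectors
#' (bandwidth = median pair distance). With a single batch the embedding is
#' returned uncorrected.
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param hvgs genes to embed (e.g. from [select_hvgs()]).
#' @param batch_key colData column defining batches (default "donor").
#' @param n_pcs number of principal components (default 50).
#' @param k neighbors per direction for the mutual search (default 20).
#' @return list with `embedding` (cells x n_pcs corrected coordinates),
#'   `raw` (uncorrected), and `batch` labels.
#' @export
correct_batch <- function(sce, hvgs, batch_key = "donor", n_pcs = 50, k = 20) {
  lc <- .logcounts(sce)
  hvgs <- intersect(hvgs, rownames(lc))
  X <- t(as.matrix(lc[hvgs, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(X) - 1, nrow(X) - 1)
  pca <- stats::prcomp(X, rank. = n_pcs, center = TRUE, scale. = FALSE)
  coords <- pca$x
  batch <- as.character(SummarizedExperiment::colData(sce)[[batch_key]])
  if (is.null(batch)) stop("batch key not found in colData")
  levels_in_order <- unique(batch)
  if (length(levels_in_order) == 1) {
    return(list(embedding = coords, raw = coords, batch = batch))
  }
  if (any(table(batch) < k)) stop("a batch has fewer than k cells")

  corrected <- coords
  ref_idx <- which(batch == levels_in_order[1])
  for (b in levels_in_order[-1]) {
    bi <- which(batch == b)
    ref <- corrected[ref_idx, , drop = FALSE]
    inc <- corrected[bi, , drop = FALSE]
    d <- as.matrix(stats::dist(rbind(ref, inc)))
    nr <- nrow(ref)
    cross <- d[seq_len(nr), nr + seq_along(bi), drop = FALSE]
    # k nearest in each direction
    nn_ref_to_inc <- apply(cross, 1, function(x) order(x)[seq_len(k)])
    nn_inc_to_ref <- apply(cross, 2, function(x) order(x)[seq_len(k)])
    pairs <- which(vapply(seq_len(nr), function(i) {
      any(vapply(nn_ref_to_inc[, i], function(j) i %in% nn_inc_to_ref[, j],
                 logical(1)))
    }, logical(1)))
    pair_list <- do.call(rbind, lapply(seq_len(nr), function(i) {
      js <- nn_ref_to_inc[, i]
      js <- js[vapply(js, function(j) i %in% nn_inc_to_ref[, j], logical(1))]
      if (length(js)) cbind(i, js) else NULL
    }))
    if (is.null(pair_list) || nrow(pair_list) == 0) next
    diffs <- ref[pair_list[, 1], , drop = FALSE] - inc[pair_list[, 2], , drop = FALSE]
    anchor <- inc[pair_list[, 2], , drop = FALSE]
    d_inc <- as.matrix(stats::dist(rbind(inc, anchor)))
    dd <- d_inc[seq_len(nrow(inc)), nrow(inc) + seq_len(nrow(anchor)), drop = FALSE]
    sigma <- stats::median(dd[dd > 0])
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
    w <- exp(-dd^2 / (2 * sigma^2))
    w <- w / pmax(rowSums(w), .Machine$double.eps)
    corrected[bi, ] <- inc + w %*% diffs
    ref_idx <- c(ref_idx, bi)
  }
  list(embedding = corrected, raw = coords, batch = batch)
}

#' Shared-nearest-neighbor graph clustering with Louvain
#'
#' k-nearest neighbors by Euclidean distance in the embedding (ties broken by
#' cell order), SNN edge weights as the Jaccard index of the two neighbor
#' sets, zero-weight edges dropped, then seeded Louvain modularity
#' optimization. Labels 0..C-1 are ordered by decreasing cluster size.
#'
#' @param embedding cells x dims numeric matrix.
#' @param k neighbors (default 5).
#' @param seed Louvain seed.
#' @param resolution Louvain resolution (default 1).
#' @return named integer vector of cluster labels, plus the modularity in
#'   `attr(, "modularity")`.
#' @export
snn_louvain <- function(embedding, k = 5, seed = 1, resolution = 1) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be < number of cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(x) order(x)[seq_len(k)]))
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(nn)), x = 1,
    dims = c(n, n)
  )
  inter <- Matrix::tcrossprod(M)
  jac <- inter
  jac@x <- jac@x / (2 * k - jac@x)
  diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE,
                                           diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- relabel[as.character(memb)]
  names(out) <- rownames(embedding)
  attr(out, "modularity") <- igraph::modularity(cl)
  out
}

#' Correlation-based label transfer against reference profiles
#'
#' Each cell is assigned the reference label with the highest Spearman
#' correlation over the intersection of the supplied genes and the reference
#' genes (a deliberately simplified nearest-profile classifier without
#' iterative fine-tuning).
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param reference_profiles gene x label numeric matrix (>= 2 labels).
#' @param genes genes to correlate over (e.g. HVGs); default all.
#' @param score_floor correlations below this are flagged low-confidence.
#' @return data.frame: cell, label, score, low_confidence.
#' @export
label_transfer <- function(sce, reference_profiles, genes = NULL,
                           score_floor = 0.2) {
  if (ncol(reference_profiles) < 2) stop("need >= 2 reference labels")
  lc <- .logcounts(sce)
  genes <- intersect(genes %||% rownames(lc), rownames(reference_profiles))
  genes <- intersect(genes, rownames(lc))
  if (length(genes) < 50) stop("insufficient gene overlap with the reference (< 50)")
  expr_ranks <- apply(as.matrix(lc[genes, , drop = FALSE]), 2, rank)
  ref_ranks <- apply(reference_profiles[genes, , drop = FALSE], 2, rank)
  cors <- stats::cor(expr_ranks, ref_ranks)
  best <- max.col(cors, ties.method = "first")
  data.frame(
    cell = colnames(lc),
    label = colnames(reference_profiles)[best],
    score = cors[cbind(seq_len(nrow(cors)), best)],
    low_confidence = cors[cbind(seq_len(nrow(cors)), best)] < score_floor,
    stringsAsFactors = FALSE
  )
}

# AUC of `x` separating group a (positive) from group b via the rank-sum
# identity; ties contribute 0.5 through midranks
.auc_vec <- function(xa, xb) {
  n1 <- ncol(xa)
  n2 <- ncol(xb)
  r <- t(apply(cbind(xa, xb), 1, rank))
  u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Per-gene per-cluster mean pairwise AUC marker scores
#'
#' For each gene and cluster, the AUC of the gene's expression separating
#' that cluster from each other cluster (Mann-Whitney U over n1*n2, midrank
#' ties at 0.5), averaged across the comparisons.
#'
#' @param sce a normalized `SingleCellExperiment` (falls back to counts if no
#'   log layer).
#' @param labels per-cell cluster labels (>= 2 non-empty clusters).
#' @return list with `auc` (gene x cluster matrix of mean AUC) and `top`
#'   (function(cluster, n) returning the n top markers by decreasing AUC).
#' @export
score_markers <- function(sce, labels) {
  x <- if ("logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    .logcounts(sce)
  } else {
    .counts(sce)
  }
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) < 2) stop("need >= 2 clusters")
  if (any(table(labels) == 0)) stop("empty cluster")
  x <- as.matrix(x)
  auc <- matrix(NA_real_, nrow(x), length(lv), dimnames = list(rownames(x), lv))
  for (a in lv) {
    xa <- x[, labels == a, drop = FALSE]
    others <- setdiff(lv, a)
    acc <- matrix(0, nrow(x), length(others))
    for (j in seq_along(others)) {
      xb <- x[, labels == others[j], drop = FALSE]
      acc[, j] <- .auc_vec(xa, xb)
    }
    auc[, a] <- rowMeans(acc)
  }
  top <- function(cluster, n) {
    o <- order(-auc[, cluster], rownames(auc))
    rownames(auc)[o[seq_len(min(n, nrow(auc)))]]
  }
  list(auc = auc, top = top)
}
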