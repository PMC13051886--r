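#' Aggregate single-cell counts into per-donor pseudobulks
#'
#' Gene-wise sums of the counts of each donor's cells; donors contributing
#' fewer than `min_cells` cells are dropped with a warning. Group labels are
#' inherited from the cells and must be unique within a donor.
#'
#' @param sce a `SingleCellExperiment` with `donor` and `group` in colData.
#' @param min_cells minimum cells per kept donor (default 10).
#' @return object of class `Pseudobulk`: list with `counts` (gene x donor
#'   matrix), `donors` (donor, group, n_cells), `lib_size`.
#' @export
pseudobulk <- function(sce, min_cells = 10) {
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$donor) || is.null(cd$group)) {
    stop("colData needs 'donor' and 'group'")
  }
  donor <- as.character(cd$donor)
  mixed <- tapply(as.character(cd$group), donor, function(g) length(unique(g)))
  if (any(mixed > 1)) {
    stop("donors with mixed group labels: ",
         paste(names(mixed)[mixed > 1], collapse = ", "))
  }
  counts <- .counts(sce)
  ind <- Matrix::sparseMatrix(
    i = seq_len(ncol(counts)),
    j = match(donor, unique(donor)),
    x = 1, dims = c(ncol(counts), length(unique(donor)))
  )
  sums <- as.matrix(counts %*% ind)
  colnames(sums) <- unique(donor)
  rownames(sums) <- rownames(counts)
  n_cells <- as.vector(table(donor)[unique(donor)])
  keep <- n_cells >= min_cells
  if (!all(keep)) {
    warning("dropping donors with < ", min_cells, " cells: ",
            paste(unique(donor)[!keep], collapse = ", "))
  }
  donors <- data.frame(
    donor = unique(donor)[keep],
    group = as.character(cd$group)[match(unique(donor)[keep], donor)],
    n_cells = n_cells[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = sums[, keep, drop = FALSE], donors = donors,
         lib_size = colSums(sums[, keep, drop = FALSE])),
    class = "Pseudobulk"
  )
}

#' Trimmed mean of M-values normalization factors
#'
#' The reference column is the one whose upper-quartile/library-size ratio is
#' closest to the mean ratio. For every column, M (log2 depth-normalized
#' ratios vs the reference) and A (average log abundance) are computed over
#' genes expressed in both; after trimming the top and bottom `trim_m` of M
#' and `trim_a` of A, the factor is 2 to the inverse-variance-weighted mean of
#' the remaining M values. Factors are rescaled to geometric mean 1.
#'
#' @param pb a [pseudobulk()] object (or any gene x sample count matrix via
#'   `pb$counts`).
#' @param trim_m,trim_a trim fractions for M and A (defaults 0.3 / 0.05).
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(pb, trim_m = 0.3, trim_a = 0.05) {
  counts <- if (inherits(pb, "Pseudobulk")) pb$counts else as.matrix(pb)
  if (ncol(counts) < 2) stop("need >= 2 columns")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero column present")
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref_i <- which.min(abs(uq - mean(uq)))
  refc <- counts[, ref_i]
  lib_r <- lib[ref_i]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    lib_o <- lib[j]
    ok <- obs > 0 & refc > 0
    if (j == ref_i || !any(ok)) return(1)
    M <- log2((obs[ok] / lib_o) / (refc[ok] / lib_r))
    A <- 0.5 * log2((obs[ok] / lib_o) * (refc[ok] / lib_r))
    v <- (lib_o - obs[ok]) / (lib_o * obs[ok]) +
      (lib_r - refc[ok]) / (lib_r * refc[ok])
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(counts))
}

#' Pseudobulk negative-binomial quasi-likelihood differential expression
#'
#' Genes detected (CPM above `min_cpm`) in at least as many samples as the
#' smaller group are tested with an NB GLM per gene and the quasi-likelihood
#' F-test (edgeR's trended/tagwise dispersion estimation and QL dispersion
#' squeezing), with offsets `log(lib_size * norm_factor)`. Storey q-values
#' are attached alongside BH-adjusted p.
#'
#' @param pb a [pseudobulk()] object with >= 2 donors per group.
#' @param norm_factors optional normalization factors (defaults to
#'   [tmm_factors()]).
#' @param min_cpm detection threshold in counts per million (default 1).
#' @return `PseudobulkDEResult`, a `DEResult`-compatible list whose table has
#'   feature, log2FC, dispersion, F, t (signed sqrt F), p, q, adj_p,
#'   mean_expr (average logCPM).
#' @export
nb_ql_test <- function(pb, norm_factors = NULL, min_cpm = 1) {
  stopifnot(inherits(pb, "Pseudobulk"))
  grp <- pb$donors$group
  if (length(unique(grp)) != 2) stop("exactly two groups required")
  if (any(table(grp) < 2)) stop("each group needs >= 2 donors (no replication)")
  lev <- if ("control" %in% grp) c("control", setdiff(unique(grp), "control")) else unique(grp)
  group <- factor(grp, levels = lev)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(pb)

  y <- edgeR::DGEList(counts = pb$counts, group = group)
  y$samples$norm.factors <- unname(norm_factors[colnames(pb$counts)])
  keep <- rowSums(edgeR::cpm(y) > min_cpm) >= min(table(group))
  y <- y[keep, , keep.lib.sizes = TRUE]
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  tt <- qlf$table
  st <- storey_qvalue(tt$PValue)
  tab <- data.frame(
    feature = rownames(tt),
    log2FC = tt$logFC,
    dispersion = y$tagwise.dispersion,
    F = tt$F,
    t = sign(tt$logFC) * sqrt(pmax(tt$F, 0)),
    p = tt$PValue,
    q = st$q,
    adj_p = bh_adjust(tt$PValue),
    mean_expr = tt$logCPM,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, qmodel = st$model,
         params = list(df_prior = fit$df.prior,
                       norm_factors = norm_factors)),
    class = c("PseudobulkDEResult", "DEResult")
  )
}
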