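#' Transcription-factor activity from multivariate regression-tree ensembles
#'
#' For each cell, a seeded random-forest of shallow regression trees predicts
#' the cell's expression vector (over genes) from the gene x TF signed-weight
#' membership matrix of the regulatory network; a TF's activity in that cell
#' is its total impurity-reduction importance, normalized to sum 1 across
#' TFs. Cells with constant expression are degenerate and receive uniform
#' activities with a flag.
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param net data.frame with columns tf, target, weight (nonzero, finite).
#' @param n_trees,max_depth ensemble size and tree depth (defaults 100 / 3).
#' @param seed integer seed (one seeded generator per call).
#' @param min_targets TFs with fewer targets present in the data are dropped
#'   with a warning (default 5).
#' @return `ActivityMatrix`: list with `activity` (TF x cell), `degenerate`
#'   (logical per cell), `params`.
#' @export
tf_activity_mdt <- function(sce, net, n_trees = 100, max_depth = 3, seed = 1,
                            min_targets = 5) {
  stopifnot(all(c("tf", "target", "weight") %in% names(net)))
  if (any(!is.finite(net$weight) | net$weight == 0)) {
    stop("network weights must be finite and nonzero")
  }
  lc <- .logcounts(sce)
  genes <- rownames(lc)
  net <- net[net$target %in% genes, , drop = FALSE]
  n_targets <- table(net$tf)
  keep_tf <- names(n_targets)[n_targets >= min_targets]
  dropped <- setdiff(unique(net$tf), keep_tf)
  if (length(dropped)) {
    warning("TFs with < ", min_targets, " targets dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep_tf) < 2) stop("fewer than 2 usable TFs in the network")
  net <- net[net$tf %in% keep_tf, , drop = FALSE]
  X <- matrix(0, length(genes), length(keep_tf),
              dimnames = list(genes, keep_tf))
  X[cbind(match(net$target, genes), match(net$tf, keep_tf))] <- net$weight
  Xdf <- as.data.frame(X)
  names(Xdf) <- make.names(keep_tf)

  n_cells <- ncol(lc)
  act <- matrix(0, length(keep_tf), n_cells,
                dimnames = list(keep_tf, colnames(lc)))
  degen <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    y <- as.numeric(lc[, i])
    if (stats::var(y) == 0) {
      degen[i] <- TRUE
      act[, i] <- 1 / length(keep_tf)
      next
    }
    rf <- ranger::ranger(
      x = Xdf, y = y, num.trees = n_trees, max.depth = max_depth,
      importance = "impurity", replace = TRUE, seed = seed,
      num.threads = 1
    )
    imp <- pmax(rf$variable.importance, 0)
    s <- sum(imp)
    act[, i] <- if (s > 0) imp / s else 1 / length(keep_tf)
    if (s == 0) degen[i] <- TRUE
  }
  structure(
    list(activity = act, degenerate = degen,
         params = list(n_trees = n_trees, max_depth = max_depth, seed = seed,
                       min_targets = min_targets)),
    class = "ActivityMatrix"
  )
}

#' Donor-mean TF activity and between-group Welch tests
#'
#' Averages each TF's activity across the cells of every donor and compares
#' donor means between groups with Welch's t, with a per-group Shapiro-Wilk
#' screen. Per-TF p-values are reported without multiplicity correction
#' (flagged); a BH column is provided for convenience.
#'
#' @param act an `ActivityMatrix` (see [tf_activity_mdt()]).
#' @param meta data.frame with cell, donor, group (one row per scored cell).
#' @return list with `donor_means` (TF x donor) and `tests` (tf, mean per
#'   group, t, df, p, adj_p, shapiro flags).
#' @export
donor_mean_activity <- function(act, meta) {
  stopifnot(inherits(act, "ActivityMatrix"))
  meta <- meta[match(colnames(act$activity), meta$cell), , drop = FALSE]
  if (anyNA(meta$cell)) stop("metadata does not cover all scored cells")
  donor <- as.character(meta$donor)
  donors <- unique(donor)
  dm <- sapply(donors, function(d) rowMeans(act$activity[, donor == d, drop = FALSE]))
  grp <- as.character(meta$group)[match(donors, donor)]
  if (any(table(grp) < 2)) stop("need >= 2 donors per group")
  lv <- if ("control" %in% grp) c("control", setdiff(unique(grp), "control")) else unique(grp)
  tests <- do.call(rbind, lapply(rownames(dm), function(tf) {
    gt <- group_test(dm[tf, ], factor(grp, levels = lv))
    data.frame(
      tf = tf,
      mean_1 = gt$means[1], mean_2 = gt$means[2],
      t = gt$t, df = gt$df, p = gt$p,
      shapiro_flag = gt$normality_flag,
      stringsAsFactors = FALSE
    )
  }))
  names(tests)[2:3] <- paste0("mean_", lv)
  tests$adj_p <- bh_adjust(tests$p)
  attr(tests, "multiplicity") <- "per-TF p-values uncorrected by design; adj_p is informational"
  list(donor_means = dm, tests = tests, groups = stats::setNames(grp, donors))
}

#' AUC recovery-curve signature scores per cell
#'
#' Each cell's genes are ranked by descending raw count, ties broken by one
#' seeded random permutation fixed for the whole run (so zero-inflated counts
#' do not bias the score deterministically). The recovery curve counts
#' signature genes within the top x ranks for x up to
#' `ceiling(top_fraction * n_genes)`; the score is the area under that step
#' curve normalized by the maximum achievable area (all signature genes at
#' the very top), giving values in \[0, 1\].
#'
#' @param sce a `SingleCellExperiment` (raw counts are ranked).
#' @param signature character vector of signature genes (>= 1 present).
#' @param top_fraction fraction of the ranking examined, in (0, 0.5\]
#'   (default 0.05).
#' @param seed seed for the tie-break permutation.
#' @return `SignatureScoreTable`: data.frame cell, auc; the signature,
#'   top_fraction and seed ride along as attributes.
#' @export
aucell_score <- function(sce, signature, top_fraction = 0.05, seed = 1) {
  if (top_fraction <= 0 || top_fraction > 0.5) {
    stop("top_fraction must lie in (0, 0.5]")
  }
  counts <- .counts(sce)
  sig <- intersect(signature, rownames(counts))
  if (length(sig) == 0) stop("no signature gene present in the dataset")
  n_genes <- nrow(counts)
  M <- ceiling(top_fraction * n_genes)
  S <- length(sig)
  sig_idx <- match(sig, rownames(counts))
  max_area <- if (S >= M) M * (M + 1) / 2 else S * (S + 1) / 2 + (M - S) * S

  tie_perm <- with_seed(seed, sample.int(n_genes))
  n_cells <- ncol(counts)
  auc <- numeric(n_cells)
  inv <- integer(n_genes)
  chunk <- 512L
  for (start in seq.int(1L, n_cells, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_cells)
    block <- as.matrix(counts[, idx, drop = FALSE])
    for (jj in seq_along(idx)) {
      o <- order(-block[, jj], tie_perm)
      inv[o] <- seq_len(n_genes)
      pos <- inv[sig_idx]
      hit <- pos[pos <= M]
      auc[idx[jj]] <- sum(M - hit + 1) / max_area
    }
  }
  out <- data.frame(cell = colnames(counts), auc = auc,
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- sig
  attr(out, "top_fraction") <- top_fraction
  attr(out, "seed") <- seed
  class(out) <- c("SignatureScoreTable", "data.frame")
  out
}

#' Threshold AUC scores into binary program labels
#'
#' `label = (AUC >= threshold)`. The default thresholds used downstream are
#' 0.17 for the CD8 Treg signature and 0.22 for Tc17, chosen from the score
#' distribution and the anticipated blood frequencies of the two programs.
#'
#' @param scores a `SignatureScoreTable`.
#' @param threshold numeric in \[0, 1\].
#' @return named logical vector per cell.
#' @export
classify_cells <- function(scores, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  stats::setNames(scores$auc >= threshold, scores$cell)
}

#' Default AUC thresholds for the shipped signatures
#' @return named numeric vector (Treg = 0.17, Tc17 = 0.22).
#' @export
default_auc_thresholds <- function() c(Treg = 0.17, Tc17 = 0.22)

#' Verify a classified population through marker overrepresentation
#'
#' Markers of the positive class are ranked by decreasing mean pairwise AUC
#' (see [score_markers()]); the top `top_n` feed a hypergeometric ORA against
#' the supplied pathway sets with the full scored gene universe.
#'
#' @param sce a normalized `SingleCellExperiment`.
#' @param labels logical per-cell vector (positive class >= 5 cells).
#' @param pathway_sets named list of gene sets.
#' @param top_n markers taken forward (default 250).
#' @param adj_p_max BH cutoff for the enriched subset (default 0.1).
#' @param min_size minimum pathway size.
#' @return list: `markers` (character), `ora` (full table), `enriched`
#'   (rows with adj_p < adj_p_max).
#' @export
verify_signature_markers <- function(sce, labels, pathway_sets, top_n = 250,
                                     adj_p_max = 0.1, min_size = 8) {
  labels <- as.logical(labels)
  if (sum(labels) < 5) stop("positive class has < 5 cells")
  if (sum(!labels) < 1) stop("negative class is empty")
  sm <- score_markers(sce, ifelse(labels, "pos", "neg"))
  markers <- sm$top("pos", top_n)
  ora <- ora_hypergeometric(markers, rownames(sm$auc), pathway_sets,
                            min_size = min_size)
  list(markers = markers, ora = ora,
       enriched = ora[ora$adj_p < adj_p_max, , drop = FALSE])
}

#' Compare per-donor program frequencies between groups
#'
#' The per-donor fraction of positively labeled cells is compared between
#' groups with Welch's t (Shapiro-Wilk screened, not enforced). Donors with
#' fewer than `min_cells` cells are excluded with a warning.
#'
#' @param labels named logical vector per cell (see [classify_cells()]).
#' @param meta data.frame with cell, donor, group.
#' @param min_cells minimum cells per donor (default 10).
#' @return list: `fractions` (donor, group, n_cells, fraction) and `test`
#'   (the [group_test()] result on the fractions).
#' @export
compare_frequencies <- function(labels, meta, min_cells = 10) {
  meta <- meta[match(names(labels), meta$cell), , drop = FALSE]
  if (anyNA(meta$cell)) stop("metadata does not cover all labeled cells")
  donor <- as.character(meta$donor)
  tab <- data.frame(
    donor = unique(donor),
    group = as.character(meta$group)[match(unique(donor), donor)],
    n_cells = as.vector(table(donor)[unique(donor)]),
    fraction = as.vector(tapply(labels, donor, mean)[unique(donor)]),
    stringsAsFactors = FALSE
  )
  drop <- tab$n_cells < min_cells
  if (any(drop)) {
    warning("excluding donors with < ", min_cells, " cells: ",
            paste(tab$donor[drop], collapse = ", "))
    tab <- tab[!drop, , drop = FALSE]
  }
  if (any(table(tab$group) < 2)) stop("need >= 2 donors per group")
  lv <- if ("control" %in% tab$group) {
    c("control", setdiff(unique(tab$group), "control"))
  } else unique(tab$group)
  list(fractions = tab,
       test = group_test(tab$fraction, factor(tab$group, levels = lv)))
}
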