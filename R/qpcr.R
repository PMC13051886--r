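#' Rank housekeeping candidates and select a normalizer
#'
#' For each candidate feature of a log2 expression matrix: the coefficient of
#' variation on the linear scale (`sd/mean` of `2^log2`), the two-sided Welch
#' p-value between groups, and the mean-expression rank. The selected
#' normalizer minimizes CV among candidates that are invariable between
#' conditions (Welch p > 0.5, a deliberately conservative cut) and highly
#' expressed (top quartile of mean expression).
#'
#' @param m an [expression_matrix()].
#' @param candidates character vector of feature ids, or "all".
#' @return data.frame (sorted by CV): feature, cv, group_p, mean_rank,
#'   eligible, selected. Errors, listing the best near-misses, when no
#'   candidate passes both filters.
#' @export
select_housekeeping <- function(m, candidates = "all") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2) stop("need >= 2 samples")
  feats <- if (identical(candidates, "all")) rownames(m$values) else candidates
  missing <- setdiff(feats, rownames(m$values))
  if (length(missing)) stop("unknown candidates: ", paste(missing, collapse = ", "))
  lin <- 2^m$values[feats, , drop = FALSE]
  cv <- apply(lin, 1, stats::sd) / rowMeans(lin)
  grp <- m$samples$group
  group_p <- apply(m$values[feats, , drop = FALSE], 1, function(x) {
    a <- x[grp == "case"]
    b <- x[grp == "control"]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  })
  all_means <- rowMeans(m$values)
  mean_rank <- rank(-all_means)[feats]
  top_quartile <- all_means[feats] >= stats::quantile(all_means, 0.75)
  eligible <- group_p > 0.5 & top_quartile
  report <- data.frame(
    feature = feats, cv = cv, group_p = group_p, mean_rank = mean_rank,
    eligible = eligible, selected = FALSE, stringsAsFactors = FALSE
  )
  report <- report[order(report$cv), , drop = FALSE]
  rownames(report) <- NULL
  if (!any(eligible)) {
    near <- utils::head(report, 3)
    stop("no candidate is both group-invariant (p > 0.5) and highly ",
         "expressed; best near-misses: ",
         paste(sprintf("%s (cv %.3g, p %.3g)", near$feature, near$cv,
                       near$group_p), collapse = "; "))
  }
  report$selected[which(report$eligible)[1]] <- TRUE
  report
}

#' Fit an amplification-efficiency standard curve
#'
#' Ordinary least squares of Ct on log10(dilution);
#' `E% = (10^(-1/slope) - 1) * 100`, so a slope of -3.3219 (= -1/log10(2))
#' gives exactly 100%. Primer pairs are flagged usable when `r^2 > 0.99`.
#'
#' @param standards qPCR table rows with a non-missing `dilution` column.
#' @param assay optional assay id to subset on.
#' @return list of class `EfficiencyFit`: assay, slope, intercept, r_squared,
#'   efficiency_percent, pass.
#' @export
fit_efficiency <- function(standards, assay = NULL) {
  if (!is.null(assay)) standards <- standards[standards$assay == assay, , drop = FALSE]
  standards <- standards[!is.na(standards$dilution), , drop = FALSE]
  if (length(unique(standards$dilution)) < 3) {
    stop("need >= 3 distinct dilutions for a standard curve")
  }
  fit <- stats::lm(ct ~ I(log10(dilution)), data = standards)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((standards$ct - mean(standards$ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(
    list(
      assay = assay %||% paste(unique(standards$assay), collapse = ","),
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      efficiency_percent = (10^(-1 / slope) - 1) * 100,
      pass = r2 > 0.99
    ),
    class = "EfficiencyFit"
  )
}

#' Relative quantification by the 2^-ddCt method
#'
#' Replicate Cts are averaged per (sample, assay); `dCt = Ct_target -
#' Ct_reference`; `ddCt = dCt - mean(dCt over control samples)`;
#' `fold = 2^-ddCt`. By construction the control-group folds have geometric
#' mean 1.
#'
#' @param tab qPCR table (sample, group, assay, replicate, ct); standard rows
#'   (non-missing dilution) are ignored.
#' @param target,reference assay ids.
#' @param control_group group label anchoring ddCt (default "control").
#' @return data.frame per sample: sample, group, dct, ddct, fold.
#' @export
ddct <- function(tab, target, reference, control_group = "control") {
  tab <- tab[is.na(tab$dilution) | is.null(tab$dilution), , drop = FALSE]
  tab <- tab[tab$assay %in% c(target, reference), , drop = FALSE]
  agg <- stats::aggregate(ct ~ sample + group + assay, data = tab, FUN = mean)
  wide <- merge(
    agg[agg$assay == target, c("sample", "group", "ct")],
    agg[agg$assay == reference, c("sample", "ct")],
    by = "sample", all = TRUE, suffixes = c("_target", "_reference")
  )
  bad <- wide$sample[is.na(wide$ct_target) | is.na(wide$ct_reference)]
  if (length(bad)) {
    stop("samples missing one of the assays: ", paste(bad, collapse = ", "))
  }
  if (!any(wide$group == control_group)) stop("control group is empty")
  wide$dct <- wide$ct_target - wide$ct_reference
  wide$ddct <- wide$dct - mean(wide$dct[wide$group == control_group])
  wide$fold <- 2^(-wide$ddct)
  out <- wide[order(wide$sample), c("sample", "group", "dct", "ddct", "fold")]
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison with a normality screen
#'
#' Welch t with Satterthwaite degrees of freedom; Shapiro-Wilk per group is
#' reported (and flagged below 0.05) but never enforced.
#'
#' @param values numeric vector (e.g. per-sample dCt).
#' @param groups parallel group labels (exactly two levels).
#' @return list: t, df, p, group means, shapiro_p (named per group),
#'   normality_flag.
#' @export
group_test <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: both groups constant
    wt <- list(statistic = if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf,
               parameter = length(x) + length(y) - 2,
               p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    wt <- stats::t.test(x, y, var.equal = FALSE)
  }
  sh <- vapply(list(x, y), function(v) {
    if (length(v) >= 3 && stats::sd(v) > 0) stats::shapiro.test(v)$p.value
    else NA_real_
  }, numeric(1))
  names(sh) <- lv
  list(
    t = unname(wt$statistic), df = unname(wt$parameter), p = wt$p.value,
    means = stats::setNames(c(mean(x), mean(y)), lv),
    shapiro_p = sh,
    normality_flag = any(!is.na(sh) & sh < 0.05)
  )
}

#' Pearson correlation between paired dCt series
#'
#' @param x,y paired numeric vectors (>= 3 values, non-degenerate).
#' @return list with `r` and two-sided t-based `p`.
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
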