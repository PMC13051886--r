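#' Hypergeometric overrepresentation analysis
#'
#' For every set with at least `min_size` members inside the universe, the
#' upper-tail hypergeometric probability `P(X >= overlap)` of the observed
#' overlap with the DE list is computed, with Benjamini-Hochberg adjustment
#' across the retained sets. If the DE list is split by direction the
#' directional z-score `(u - d) / sqrt(n)` is reported per set.
#'
#' @param de character vector of DE features, or a list with elements `up`
#'   and `down` (directional).
#' @param universe character vector of all tested features; `de` must be a
#'   subset.
#' @param sets named list of feature sets (see [read_gmt()]).
#' @param min_size minimum set size inside the universe (default 8).
#' @return data.frame (one row per retained set, sorted by p): set, n (set
#'   size in universe), overlap, u, d, z, p, adj_p.
#' @export
ora_hypergeometric <- function(de, universe, sets, min_size = 8) {
  if (min_size < 1) stop("min_size must be >= 1")
  if (is.list(de)) {
    de_up <- unique(de$up)
    de_down <- unique(de$down)
    de_all <- unique(c(de_up, de_down))
  } else {
    de_up <- de_down <- NULL
    de_all <- unique(de)
  }
  missing <- setdiff(de_all, universe)
  if (length(missing)) {
    stop("DE features outside the universe: ",
         paste(utils::head(missing), collapse = ", "))
  }
  universe <- unique(universe)
  N <- length(universe)
  n_de <- length(de_all)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    ov <- length(intersect(members, de_all))
    p <- stats::phyper(ov - 1, K, N - K, n_de, lower.tail = FALSE)
    u <- if (is.null(de_up)) NA_integer_ else length(intersect(members, de_up))
    d <- if (is.null(de_down)) NA_integer_ else length(intersect(members, de_down))
    z <- if (is.na(u) || is.na(d)) NA_real_ else enrichment_zscore(u, d, K)
    data.frame(set = nm, n = K, overlap = ov, u = u, d = d, z = z, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(set = character(0), n = integer(0), overlap = integer(0),
                      u = integer(0), d = integer(0), z = numeric(0),
                      p = numeric(0), adj_p = numeric(0)))
  }
  rows$adj_p <- bh_adjust(rows$p)
  rows[order(rows$p, rows$set), , drop = FALSE]
}

#' Directional enrichment z-score
#'
#' `z = (u - d) / sqrt(n)` where `u` and `d` are the up- and down-regulated
#' DE members of a category of total size `n`.
#'
#' @param u,d non-negative counts of up/down DE members.
#' @param n category size (> 0, >= max(u, d)).
#' @return numeric z.
#' @export
enrichment_zscore <- function(u, d, n) {
  if (n == 0) stop("category size n must be > 0")
  if (u < 0 || d < 0 || n < max(u, d)) stop("invalid u/d/n counts")
  (u - d) / sqrt(n)
}

# signed extremum of the GSEA running sum for one set of hit positions
# (1-based positions in the ranking); w = |stat|^p_w at those positions.
# The walk only attains its extrema immediately after a hit (local max) or
# immediately before one (local min), so those 2k values suffice.
.gsea_es <- function(positions, w, N, details = FALSE) {
  k <- length(positions)
  NR <- sum(w)
  miss_step <- 1 / (N - k)
  o <- order(positions)
  pos <- positions[o]
  wi <- w[o]
  if (NR == 0) {
    # degenerate flat weights: fall back to equal hit increments
    csum <- seq_len(k) / k
  } else {
    csum <- cumsum(wi) / NR
  }
  after <- csum - (pos - seq_len(k)) * miss_step
  before <- c(0, csum[-k]) - (pos - seq_len(k)) * miss_step
  cand <- c(after, before)
  # positive extremum wins a magnitude tie, matching the walk convention
  maxv <- max(cand)
  minv <- min(cand)
  es <- if (maxv >= -minv) maxv else minv
  if (!details) return(es)
  list(es = es, pos = pos, after = after, before = before, order = o)
}

#' Preranked gene-set enrichment analysis
#'
#' Features are ranked by the statistic in descending order (ties broken by
#' feature id). The running sum gains `|stat|^p_w / N_R` at set members and
#' loses `1 / (N - |S|)` elsewhere; the enrichment score ES is its signed
#' extremum. Significance comes from `n_perm` feature-label permutations with
#' the given seed: NES is ES over the mean absolute null ES of matching sign,
#' and p is the sign-matched `(1 + b) / (1 + B)` permutation tail. BH
#' adjustment is applied across sets.
#'
#' @param stats named numeric vector (unique feature ids) of ranking
#'   statistics.
#' @param sets named list of feature sets.
#' @param p_w weight exponent (default 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @return data.frame per scored set: set, size, ES, NES, p, adj_p,
#'   leading_edge (comma-joined members up to the extremum).
#' @export
gsea_preranked <- function(stats, sets, p_w = 1, n_perm = 1000, seed = 1) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("`stats` must have unique feature names")
  }
  if (n_perm < 100) stop("n_perm must be >= 100")
  o <- order(-stats, names(stats))
  ranked <- stats[o]
  feats <- names(ranked)
  N <- length(ranked)
  absw <- abs(ranked)^p_w

  scored <- list()
  with_seed(seed, {
    for (nm in names(sets)) {
      members <- intersect(sets[[nm]], feats)
      k <- length(members)
      if (k == 0) {
        warning("set '", nm, "' has no member in the ranking; skipped")
        next
      }
      if (k == N) stop("set '", nm, "' covers all ranked features (degenerate)")
      pos <- match(members, feats)
      det <- .gsea_es(pos, absw[pos], N, details = TRUE)
      es <- det$es

      null_es <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(N, k)
        .gsea_es(idx, absw[idx], N)
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(es)]
      if (length(same) == 0) {
        nes <- NA_real_
        p <- 1 / (1 + n_perm)
      } else {
        nes <- es / mean(abs(same))
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      }
      sorted_members <- members[det$order]
      le <- if (es >= 0) {
        sorted_members[seq_len(which.max(det$after))]
      } else {
        sorted_members[which.min(det$before):k]
      }
      scored[[nm]] <- data.frame(
        set = nm, size = k, ES = es, NES = nes, p = p,
        leading_edge = paste(sort(le), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, scored)
  if (is.null(out)) {
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), adj_p = numeric(0),
                      leading_edge = character(0)))
  }
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p, out$set), c("set", "size", "ES", "NES", "p", "adj_p", "leading_edge")]
}

#' Signed -log10 p ranking statistic
#'
#' `score = -log10(p) * sign(log2FC)`, with p clamped at 1e-300. This is the
#' descending-order ranking used for pseudobulk GSEA.
#'
#' @param r a `DEResult`.
#' @return named numeric vector of scores (names = features).
#' @export
rank_by_signed_logp <- function(r) {
  stopifnot(inherits(r, "DEResult"))
  p <- pmax(r$table$p, 1e-300)
  stats::setNames(-log10(p) * sign(r$table$log2FC), r$table$feature)
}
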