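#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around `p.adjust(method = "BH")` that enforces the module
#' contract (non-empty input, p in \[0,1\]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, capped at 1, order-preserving in p.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 as
#' `mean(p > lambda) / (1 - lambda)`, smoothed with a cubic smoothing spline
#' (df = 3) and evaluated at the largest lambda, then clamped to (0, 1\].
#' `q_i = pi0 * min_{p_j >= p_i} (p_j * m / rank_j)`, which reduces exactly to
#' Benjamini-Hochberg when pi0 is fixed at 1.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param pi0 optional fixed pi0 (bypasses estimation).
#' @return list with `q` (same order as `p`) and `model` (class `QValueModel`:
#'   lambda grid, raw pi0 estimates, final pi0, smoother description).
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_raw <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (is.null(pi0)) {
    if (m >= 4 && stats::var(pi0_raw) > 0) {
      fit <- stats::smooth.spline(lambda, pi0_raw, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    } else {
      pi0 <- pi0_raw[length(pi0_raw)]
    }
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  # step-up with the same floating-point arithmetic as p.adjust's BH, so a
  # fixed pi0 = 1 reproduces it bit for bit
  o <- order(p, decreasing = TRUE)
  i <- m:1
  q <- pmin(1, cummin(pi0 * m / i * p[o]))[order(o)]
  model <- structure(
    list(lambda = lambda, pi0_raw = pi0_raw, pi0 = pi0,
         smoother = "cubic smoothing spline (df = 3) evaluated at lambda = 0.95"),
    class = "QValueModel"
  )
  list(q = q, model = model)
}
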