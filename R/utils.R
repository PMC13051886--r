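# internal helpers shared across modules

# Run code under a temporary RNG state so generators never leak global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Newton inversion of trigamma, used by the variance-shrinkage moment estimator.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense or TsparseMatrix -> dgCMatrix, loading Matrix's coercion methods first
.as_csparse <- function(x) {
  methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
}
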