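#' Bundle a log2 expression matrix with its sample annotations
#'
#' The common currency of the bulk stages: a numeric feature x sample matrix of
#' log2 intensities together with a sample annotation table carrying at least a
#' `group` column (levels "control" and "case"), and optionally `batch`,
#' `donor`, and further covariates.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples in
#'   columns (colnames matching `samples$sample`).
#' @param samples data.frame with columns `sample` and `group`; optional
#'   `batch`, `donor`.
#' @return An object of class `ExpressionMatrix` (a list with elements
#'   `values` and `samples`).
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("feature ids (rownames) must be present and unique")
  }
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("`samples` needs columns 'sample' and 'group'")
  }
  samples$sample <- as.character(samples$sample)
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!identical(colnames(values), samples$sample)) {
    samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
    if (anyNA(samples$sample)) stop("sample annotations do not cover all columns")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, samples = samples), class = "ExpressionMatrix")
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d features x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(table(x$samples$group)), table(x$samples$group)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @method dim ExpressionMatrix
#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Write / read an expression matrix as TSV with an annotation sidecar
#'
#' The matrix file has features in rows and a `feature` id column followed by
#' one column per sample; the sidecar holds one row per sample (columns
#' `sample`, `group`, and any further annotation columns).
#'
#' @param m an [expression_matrix()] object.
#' @param path path of the matrix TSV; the sidecar is written next to it as
#'   `<path>.samples.tsv` unless `sidecar` is given.
#' @param sidecar optional explicit sidecar path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(m, path, sidecar = paste0(path, ".samples.tsv")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, sidecar = paste0(path, ".samples.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  samples <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

# internal: 0/1 case indicator in annotation order
.case_indicator <- function(samples) {
  grp <- samples$group
  if (!all(grp %in% c("case", "control"))) {
    stop("sample groups must be 'case' or 'control'")
  }
  as.numeric(grp == "case")
}
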