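#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then members.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Plain TSV writers and readers for the tabular fixture formats
#'
#' Binding-site tables (`motif`, `mirna`, `gene`, `n_sites`), interaction
#' tables (`mirna`, `gene`, `evidence`, `source`, `confidence`), and qPCR Ct
#' tables (`sample`, `group`, `assay`, `replicate`, `ct`, `dilution`).
#'
#' @param x data.frame in the documented column layout.
#' @param path file path.
#' @name table-io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read single-cell counts as MatrixMarket triplets with sidecars
#'
#' The coordinate `.mtx` file (1-based indices) is accompanied by
#' `barcodes.tsv` (cell ids), `features.tsv` (gene ids), and `cells.tsv`
#' (cell metadata).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if missing).
#' @return `read_mtx_dir` returns a `SingleCellExperiment`.
#' @export
write_mtx_dir <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(.as_csparse(counts),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx_dir
#' @export
read_mtx_dir <- function(dir) {
  counts <- .as_csparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta, row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(
      mito = startsWith(rownames(counts), "MT-"), row.names = rownames(counts)
    )
  )
}

#' Write a differential-expression result table
#'
#' Fixed column order: feature, log2FC, t, p, q, adj_p, mean_expr.
#'
#' @param r a `DEResult` (see [moderated_t_test()]).
#' @param path file path.
#' @export
write_de_tsv <- function(r, path) {
  utils::write.table(
    r$table[, c("feature", "log2FC", "t", "p", "q", "adj_p", "mean_expr")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
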