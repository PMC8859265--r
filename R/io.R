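#' Read a genes-by-cells count matrix
#'
#' Supports MatrixMarket triples (a directory containing `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, or a path to the `.mtx` file with the two
#' TSVs alongside) and dense CSV/TSV with gene names in the first column and a
#' header row of cell barcodes.  MTX rows are features; CSV/TSV rows are
#' genes.
#'
#' @param path directory or file path.
#' @param format `"auto"`, `"mtx"` or `"csv"`.
#' @param allow_float keep non-integer values instead of erroring.
#' @return A sparse `dgCMatrix` with gene rownames and cell colnames.
#'   Duplicated gene identifiers are disambiguated by suffixing (`".1"`,
#'   `".2"`, ...) with a warning.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        allow_float = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      dir <- path
    } else {
      mtx <- path
      dir <- dirname(path)
    }
    if (!file.exists(mtx)) stop("no matrix.mtx found at ", path)
    m <- Matrix::readMM(mtx)
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    genes <- readLines(file.path(dir, "features.tsv"))
    # 10x-style features.tsv may carry extra tab-separated columns
    genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("features/barcodes do not match the matrix dimensions")
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    cells <- colnames(vals)
    m <- methods::as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix")
  }
  if (any(m@x < 0)) stop("count matrix contains negative entries")
  if (any(m@x != round(m@x))) {
    if (!allow_float) stop("matrix contains non-integer counts; ",
                           "use allow_float = TRUE to keep them")
  }
  if (anyDuplicated(genes)) {
    warning("duplicated gene identifiers disambiguated by suffixing")
    genes <- make.unique(genes, sep = ".")
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a count matrix in MatrixMarket or dense CSV format
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path directory (MTX triple) or `.csv` file path.
#' @return Invisibly, the path written.
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.csv$", path)) {
    df <- as.data.frame(as.matrix(counts))
    utils::write.csv(cbind(gene = rownames(counts), df), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    write_dataset(counts, truth = NULL, dir = path)
  }
  invisible(path)
}
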