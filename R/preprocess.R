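#' Pre-filter genes and cells of a raw count matrix
#'
#' Removes genes detected (count > 0) in fewer than `min_cells` cells and
#' cells detecting fewer than `min_features` genes.  Both criteria are
#' evaluated on the original matrix in a single pass -- the filters are not
#' iterated, so a gene kept because of cells that are later discarded remains
#' kept.
#'
#' @param counts genes x cells count matrix (dense or sparse) with dimnames.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @param min_features minimum number of detected genes a cell must have.
#' @return The filtered count matrix, identifier order preserved.
#' @export
prefilter <- function(counts, min_cells = 3, min_features = 200) {
  if (min_cells < 0 || min_features < 0) stop("thresholds must be >= 0")
  det <- counts > 0
  keep_genes <- Matrix::rowSums(det) >= min_cells
  keep_cells <- Matrix::colSums(det) >= min_features
  if (!any(keep_genes))
    stop("prefilter removed every gene (min_cells = ", min_cells, ")")
  if (!any(keep_cells))
    stop("prefilter removed every cell (min_features = ", min_features, ")")
  counts[keep_genes, keep_cells, drop = FALSE]
}

#' Per-cell quality-control metrics
#'
#' Computes, for each cell, the number of detected genes, the total count
#' \eqn{N_j}, and the mitochondrial count percentage
#' \eqn{100 \sum_{i \in mito} Tr_{ij} / N_j}, where the mitochondrial gene set
#' is every gene whose identifier starts with `mito_pattern`
#' (case-insensitive, covering human "MT-" and mouse "mt-").
#'
#' Cells with \eqn{N_j = 0} get `percent_mito = 0` and are flagged in the
#' `flagged_zero` column.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param mito_pattern identifier prefix of mitochondrial genes.
#' @return A data frame with one row per cell: `cell`, `n_features`,
#'   `total_counts`, `percent_mito`, `flagged_zero`.
#' @export
compute_qc_metrics <- function(counts, mito_pattern = "MT") {
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  n_features <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(toupper(rownames(counts)), toupper(mito_pattern))
  mito_counts <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else numeric(ncol(counts))
  pm <- ifelse(total > 0, 100 * mito_counts / total, 0)
  data.frame(cell = colnames(counts),
             n_features = as.integer(n_features),
             total_counts = unname(total),
             percent_mito = unname(pm),
             flagged_zero = unname(total == 0),
             stringsAsFactors = FALSE)
}

#' Quality-control cell filter
#'
#' Retains cells with `min_features <= n_features <= max_features` and
#' `percent_mito <= max_percent_mito`.  All bounds are inclusive for
#' retention: cells are removed only when strictly outside the bounds (a cell
#' with exactly 2500 detected genes or exactly 5% mitochondrial counts is
#' kept).  The gene set is unchanged.
#'
#' @param counts genes x cells count matrix.
#' @param metrics QC table from [compute_qc_metrics()], aligned with the
#'   matrix columns.
#' @param min_features,max_features retained range of detected gene counts.
#' @param max_percent_mito retained upper bound on mitochondrial percentage.
#' @return The cell-filtered count matrix.
#' @export
qc_filter_cells <- function(counts, metrics, min_features = 200,
                            max_features = 2500, max_percent_mito = 5) {
  if (!identical(metrics$cell, colnames(counts)))
    stop("metrics are not aligned with the matrix cells")
  keep <- metrics$n_features >= min_features &
    metrics$n_features <= max_features &
    metrics$percent_mito <= max_percent_mito
  if (!any(keep)) stop("QC filter removed every cell")
  counts[, keep, drop = FALSE]
}

#' Global-scaling log-normalization
#'
#' For each cell \eqn{j} with total count \eqn{N_j}, maps each count to
#' \eqn{\log(1 + s \cdot Tr_{ij} / N_j)} with scale factor \eqn{s} (default
#' \eqn{10^4}).  The pseudocount keeps zero counts at exactly zero and the
#' transform finite; the logarithm base is natural by default with base 10
#' available.
#'
#' Cells with \eqn{N_j = 0} cannot be normalized; they are dropped with a
#' warning naming them.
#'
#' @param counts genes x cells count matrix.
#' @param scale_factor positive scaling constant.
#' @param log_base `"natural"` or `"ten"`.
#' @return A list of class `normalized_matrix`: `values` (sparse genes x
#'   cells matrix of normalized expression), `scale_factor`, `log_base`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4,
                          log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  if (scale_factor <= 0) stop("scale_factor must be positive")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    bad <- colnames(counts)[total == 0]
    warning("dropping ", length(bad), " cell(s) with zero total counts: ",
            paste(utils::head(bad, 5), collapse = ", "))
    counts <- counts[, total > 0, drop = FALSE]
    total <- total[total > 0]
  }
  m <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  x <- log1p(scale_factor * m@x / total[m@j + 1L])
  if (log_base == "ten") x <- x / log(10)
  vals <- Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = x,
                               dims = dim(counts), dimnames = dimnames(counts))
  structure(list(values = vals, scale_factor = scale_factor,
                 log_base = log_base),
            class = "normalized_matrix")
}
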