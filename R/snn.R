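#' K-nearest-neighbor sets in principal component space
#'
#' For each cell, finds its `k` nearest cells by Euclidean distance in the
#' embedding.  The cell itself is excluded from the candidate list; by the
#' usual shared-nearest-neighbor convention it is then added to its own set
#' (`include_self = TRUE`), so sets have `k + 1` members.  Distance ties are
#' broken deterministically by cell index.
#'
#' @param embeddings cells x d matrix of PC scores (rownames = barcodes).
#' @param k number of neighbors, `0 < k < n_cells`.
#' @param include_self add each cell to its own neighbor set.
#' @return A list of class `neighbor_sets`: `sets` (list of sorted integer
#'   index vectors), `ids`, `k`, `include_self`.
#' @export
knn_sets <- function(embeddings, k = 20, include_self = TRUE) {
  n <- nrow(embeddings)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(embeddings))
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    sets[[i]] <- sort(if (include_self) c(i, ord) else ord)
  }
  structure(list(sets = sets, ids = rownames(embeddings), k = k,
                 include_self = include_self),
            class = "neighbor_sets")
}

#' Shared-nearest-neighbor graph with Jaccard edge weights
#'
#' Connects every pair of cells whose neighbor sets overlap, weighting the
#' edge by the Jaccard similarity
#' \eqn{|C_1 \cap C_2| / |C_1 \cup C_2|}.  Weights are stored as fractions in
#' `[0, 1]`; modularity is invariant to a uniform rescaling, so the
#' percent display convention changes nothing downstream.  Weights below
#' `prune_below` are dropped.
#'
#' @param sets a `neighbor_sets` from [knn_sets()].
#' @param prune_below pruning threshold on the Jaccard weight.
#' @return A sparse symmetric adjacency matrix (cells x cells) with barcode
#'   dimnames and no self-edges.
#' @export
snn_jaccard <- function(sets, prune_below = 1 / 15) {
  n <- length(sets$sets)
  sizes <- lengths(sets$sets)
  B <- Matrix::sparseMatrix(
    i = rep(seq_len(n), sizes),
    j = unlist(sets$sets),
    x = 1, dims = c(n, max(n, unlist(sets$sets))))
  inter <- methods::as(Matrix::tcrossprod(B), "TsparseMatrix")
  keep <- inter@i < inter@j
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  w <- inter@x[keep] / (sizes[i] + sizes[j] - inter@x[keep])
  ok <- w >= prune_below
  adj <- Matrix::sparseMatrix(i = c(i[ok], j[ok]), j = c(j[ok], i[ok]),
                              x = rep(w[ok], 2), dims = c(n, n))
  dimnames(adj) <- list(sets$ids, sets$ids)
  adj
}

#' Export a weighted graph as an edge-list data frame
#'
#' @param adj sparse symmetric adjacency matrix with dimnames.
#' @return Data frame with columns `from`, `to`, `weight` (each undirected
#'   edge once; self-loops included with their stored diagonal weight).
#' @export
graph_edge_list <- function(adj) {
  t <- methods::as(methods::as(adj, "generalMatrix"), "TsparseMatrix")
  keep <- t@i <= t@j
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(adj)))
  data.frame(from = ids[t@i[keep] + 1L], to = ids[t@j[keep] + 1L],
             weight = t@x[keep], stringsAsFactors = FALSE)
}
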