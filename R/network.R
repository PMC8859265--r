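#' Count how many clusters retain each marker gene
#'
#' A gene's frequency is the number of distinct clusters in which it is a
#' retained marker; genes appearing in two or more clusters are the
#' "frequent" (overlapping) markers.  The summed frequencies equal the
#' number of marker records, a conservation property the tests check.
#'
#' @param markers marker record table from [find_all_cluster_markers()].
#' @return Data frame (class `frequent_marker_table`) sorted by frequency
#'   descending then gene: `gene`, `frequency`, `clusters` (comma-separated),
#'   `p_adj` (comma-separated, aligned with `clusters`), `is_frequent`.
#' @export
frequent_markers <- function(markers) {
  if (nrow(markers) == 0) stop("marker table is empty")
  sp <- split(markers, markers$gene)
  out <- do.call(rbind, lapply(sp, function(df) {
    df <- df[order(df$cluster), ]
    data.frame(gene = df$gene[1],
               frequency = length(unique(df$cluster)),
               clusters = paste(df$cluster, collapse = ","),
               p_adj = paste(signif(df$p_adj_bonferroni, 4), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$is_frequent <- out$frequency >= 2
  out <- out[order(-out$frequency, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("frequent_marker_table", "data.frame")
  out
}

#' Spearman co-expression network over a gene set
#'
#' Computes midrank Spearman correlations between all pairs of the given
#' genes across all cells of the expression matrix, and keeps an edge
#' wherever \eqn{\rho \ge t} or \eqn{\rho \le -t} (inclusive).  Genes with
#' constant expression have undefined correlations and get no edges (a
#' message reports them); they remain nodes.
#'
#' @param normalized a `normalized_matrix` or genes x cells matrix.
#' @param genes gene identifiers to use as nodes (e.g. the frequent
#'   markers); default all rows.
#' @param threshold absolute correlation threshold `t`.
#' @return A list of class `correlation_network`: `nodes` (gene ids),
#'   `edges` (data frame `gene_a`, `gene_b`, `rho`), `threshold`.
#' @export
spearman_network <- function(normalized, genes = NULL, threshold = 0.5) {
  vals <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  if (nrow(vals) < 2) stop("need at least 2 genes")
  if (ncol(vals) < 3) stop("need at least 3 cells")
  x <- t(as.matrix(vals))
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    message(sum(const), " constant gene(s) have undefined correlations")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  idx <- which(abs(rho) >= threshold & upper.tri(rho), arr.ind = TRUE)
  nodes <- rownames(vals)
  edges <- data.frame(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "correlation_network")
}

# igraph object from a correlation network (unweighted; rho kept as an
# edge attribute), including isolated nodes.
.as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  if (nrow(network$edges) > 0)
    igraph::E(g)$rho <- network$edges$rho
  g
}

#' Node centrality panel of a correlation network
#'
#' On the unweighted undirected graph (edge presence only): degree;
#' betweenness centrality normalized by \eqn{2/((n-1)(n-2))}; closeness
#' \eqn{(r/\sum d) \cdot (r/(n-1))} where \eqn{r} is the number of other
#' reachable nodes and \eqn{d} their shortest-path distances (the standard
#' disconnected-graph correction); local clustering coefficient
#' \eqn{2 \cdot triangles / (deg (deg - 1))}; and the average shortest path
#' length to reachable nodes.  Isolated nodes get closeness, clustering and
#' path length 0 and are flagged.
#'
#' @param network a `correlation_network`.
#' @return Data frame (class `centrality_table`): `gene`, `degree`,
#'   `avg_shortest_path`, `betweenness`, `closeness`,
#'   `clustering_coefficient`, `isolated`.
#' @export
centrality_metrics <- function(network) {
  if (length(network$nodes) == 0) stop("network has no nodes")
  g <- .as_igraph(network)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  if (n > 2) btw <- btw * 2 / ((n - 1) * (n - 2))
  D <- igraph::distances(g)
  diag(D) <- Inf
  reach <- rowSums(is.finite(D))
  sumd <- rowSums(ifelse(is.finite(D), D, 0))
  clo <- ifelse(reach > 0, (reach / pmax(sumd, 1)) * (reach / (n - 1)), 0)
  asp <- ifelse(reach > 0, sumd / pmax(reach, 1), 0)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  out <- data.frame(gene = igraph::V(g)$name,
                    degree = as.integer(deg),
                    avg_shortest_path = unname(asp),
                    betweenness = unname(btw),
                    closeness = unname(clo),
                    clustering_coefficient = cc,
                    isolated = unname(deg == 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Rank hub genes by degree
#'
#' Sorts the centrality table by degree descending, breaking ties by
#' betweenness descending and then gene identifier, and returns the first
#' `n` rows (all rows when fewer exist).
#'
#' @param table a `centrality_table`.
#' @param n number of hubs to return.
#' @return The ranked head of the table with a `rank` column prepended.
#' @export
top_hubs <- function(table, n = 20) {
  ord <- order(-table$degree, -table$betweenness, table$gene)
  out <- table[utils::head(ord, n), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a correlation network as GraphML (rho as an edge attribute)
#'
#' @param network a `correlation_network`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(.as_igraph(network), path, format = "graphml")
  invisible(path)
}
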