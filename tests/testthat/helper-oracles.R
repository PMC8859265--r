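# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: dense double loops, exhaustive enumeration, and
# textbook formulas only.

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Textbook modularity from a dense adjacency matrix: the full ordered-pair
# double sum, evaluated with dense outer products (independent of the
# package's sparse-triplet path).
brute_modularity <- function(A, membership, gamma = 1) {
  A <- as.matrix(A)
  w <- rowSums(A)
  two_e <- sum(A)
  same <- outer(membership, membership, "==")
  sum((A - gamma * outer(w, w) / two_e)[same]) / two_e
}

# Random symmetric weighted graph (no self-loops).
random_graph <- function(n, p = 0.5, weighted = TRUE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (stats::runif(1) < p) {
        w <- if (weighted) stats::runif(1, 0.1, 2) else 1
        A[i, j] <- w; A[j, i] <- w
      }
  Matrix::Matrix(A, sparse = TRUE)
}

# BFS all-pairs shortest path lengths on an unweighted undirected edge list.
bfs_distances <- function(nodes, edges) {
  n <- length(nodes)
  adj <- stats::setNames(rep(list(character(0)), n), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- character(0)
      for (v in frontier)
        for (u in adj[[v]])
          if (!is.finite(D[s, u])) { D[s, u] <- d; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
  }
  D
}

# Full centrality panel from first principles (BFS + triangle counting).
oracle_centralities <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$gene_a[r], edges$gene_b[r]] <- 1
    A[edges$gene_b[r], edges$gene_a[r]] <- 1
  }
  deg <- rowSums(A)
  D <- bfs_distances(nodes, edges)
  diag(D) <- Inf
  clo <- asp <- cc <- btw <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]))
    r <- length(reach)
    if (r > 0) {
      clo[v] <- (r / sum(D[v, reach])) * (r / (n - 1))
      asp[v] <- sum(D[v, reach]) / r
    }
    nb <- which(A[v, ] == 1)
    if (deg[v] >= 2) {
      links <- sum(A[nb, nb]) / 2
      cc[v] <- 2 * links / (deg[v] * (deg[v] - 1))
    }
  }
  # betweenness by enumerating all shortest paths (ok for tiny graphs)
  D0 <- D
  diag(D0) <- 0
  ig_paths <- function(s, t) {
    # count shortest s-t paths through each vertex via DP on BFS layers
    sigma <- numeric(n); sigma[s] <- 1
    ord <- order(D0[s, ])
    for (v in ord) {
      if (!is.finite(D0[s, v]) || v == s) next
      preds <- which(A[v, ] == 1 & D0[s, ] == D0[s, v] - 1)
      sigma[v] <- sum(sigma[preds])
    }
    sigma
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    sig_s <- ig_paths(s, t)
    sig_t <- ig_paths(t, s)
    total <- sig_s[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + sig_s[v] * sig_t[v] / total
    }
  }
  if (n > 2) btw <- btw * 2 / ((n - 1) * (n - 2))
  data.frame(gene = nodes, degree = deg, avg_shortest_path = asp,
             betweenness = btw, closeness = clo,
             clustering_coefficient = cc, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Midrank Spearman correlation from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Unpenalized logistic log-likelihood, for optim-based oracle fits.
logistic_loglik <- function(beta, X, z) {
  eta <- drop(X %*% beta)
  sum(z * eta - log1p(exp(eta)))
}

# Small deterministic toy count matrix with named genes/cells.
toy_counts <- function() {
  m <- matrix(c(5, 0, 3, 0, 1,
                0, 0, 2, 1, 0,
                4, 4, 4, 4, 4,
                0, 1, 0, 0, 0,
                2, 3, 0, 5, 1,
                1, 0, 1, 0, 6), nrow = 6, byrow = TRUE)
  dimnames(m) <- list(c("MT-g1", "g2", "g3", "g4", "g5", "g6"),
                      paste0("c", 1:5))
  m
}
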