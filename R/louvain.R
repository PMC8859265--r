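# Graphs are sparse symmetric adjacency matrices A.  All modularity
# quantities are defined on ordered pairs: 2e = sum(A), node strength
# w_i = rowSums(A), and a diagonal entry A_ii is the self-loop weight as it
# appears in the double sum (so aggregating a community doubles its internal
# off-diagonal weight onto the diagonal, which keeps modularity exact).

#' Modularity of a graph partition
#'
#' \deqn{Q = \frac{1}{2e} \sum_{ij} \left[ A_{ij} -
#'   \gamma \frac{w_i w_j}{2e} \right] \delta(Cl_i, Cl_j)}
#' with edge weights \eqn{A_{ij}}, node strengths \eqn{w_i = \sum_j A_{ij}},
#' total weight \eqn{e = \frac12 \sum_{ij} A_{ij}}, and resolution
#' \eqn{\gamma} scaling the null-model term (\eqn{\gamma = 1} is the classic
#' definition).  \eqn{Q \in [-1, 1]}; the one-community partition always has
#' \eqn{Q = 0} at \eqn{\gamma = 1}.
#'
#' @param adj sparse symmetric adjacency matrix.
#' @param membership integer/character cluster label per node.
#' @param resolution the \eqn{\gamma} multiplier on the null term.
#' @return The scalar modularity Q.
#' @export
modularity_q <- function(adj, membership, resolution = 1) {
  if (length(membership) != nrow(adj))
    stop("membership must cover all nodes")
  two_e <- sum(adj)
  if (two_e <= 0) stop("graph has no edge weight")
  t <- methods::as(methods::as(adj, "generalMatrix"), "TsparseMatrix")
  comm <- as.integer(factor(membership))
  intra <- sum(t@x[comm[t@i + 1L] == comm[t@j + 1L]])
  w <- Matrix::rowSums(adj)
  W <- tapply(w, comm, sum)
  intra / two_e - resolution * sum((W / two_e)^2)
}

#' Modularity gain of inserting an isolated node into a community
#'
#' Evaluates the standard Louvain move gain: with node `node` currently
#' isolated (removed from any community), the change in Q from joining
#' `community` is
#' \deqn{\Delta Q = \frac{k_{i,Cl}}{e} -
#'   \gamma \frac{w_i \Sigma_{tot}}{2 e^2}}
#' where \eqn{k_{i,Cl}} is the weight from the node to the community,
#' \eqn{\Sigma_{tot}} the total strength of the community's members, and
#' \eqn{w_i} the node's strength.  Equals the difference of [modularity_q()]
#' before/after the move exactly.
#'
#' @param adj sparse symmetric adjacency matrix.
#' @param membership current labels, with `node` in a singleton community.
#' @param node node index.
#' @param community target community label (must exist in `membership`).
#' @param resolution the \eqn{\gamma} multiplier.
#' @return The scalar gain \eqn{\Delta Q}.
#' @export
modularity_gain <- function(adj, membership, node, community,
                            resolution = 1) {
  members <- which(membership == community & seq_along(membership) != node)
  if (length(members) == 0 && !any(membership == community))
    stop("unknown community: ", community)
  two_e <- sum(adj)
  w <- Matrix::rowSums(adj)
  k_ic <- sum(adj[node, members])
  sigma_tot <- sum(w[members])
  2 * k_ic / two_e - resolution * 2 * w[node] * sigma_tot / two_e^2
}

# One Louvain local-moving phase.  Nodes are swept in a seeded-shuffle order;
# each node moves to the neighbouring community with the largest positive
# gain relative to staying put (ties toward the lowest community index).
# Returns the integer membership (labels are node indices).
.louvain_phase1 <- function(adj, resolution) {
  n <- nrow(adj)
  t <- methods::as(methods::as(adj, "generalMatrix"), "TsparseMatrix")
  nbr_j <- split(t@j + 1L, factor(t@i + 1L, levels = seq_len(n)))
  nbr_x <- split(t@x, factor(t@i + 1L, levels = seq_len(n)))
  w <- Matrix::rowSums(adj)
  two_e <- sum(adj)
  comm <- seq_len(n)
  wtot <- w                              # per-community total strength
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      wtot[ci] <- wtot[ci] - w[i]
      js <- nbr_j[[i]]; xs <- nbr_x[[i]]
      keep <- js != i
      js <- js[keep]; xs <- xs[keep]
      cand <- comm[js]
      k_ic <- vapply(split(xs, cand), sum, 0)
      cand_ids <- as.integer(names(k_ic))
      if (!(ci %in% cand_ids)) {
        cand_ids <- c(cand_ids, ci)
        k_ic <- c(k_ic, 0)
      }
      gain <- 2 * k_ic / two_e -
        resolution * 2 * w[i] * wtot[cand_ids] / two_e^2
      rel <- gain - gain[match(ci, cand_ids)]
      best <- which(rel == max(rel))
      target <- min(cand_ids[best])
      if (max(rel) > 1e-12 && target != ci) {
        comm[i] <- target
        improved <- TRUE
      }
      wtot[comm[i]] <- wtot[comm[i]] + w[i]
    }
    if (!improved) break
  }
  comm
}

#' Aggregate a graph by a partition
#'
#' Builds the community-level graph of Louvain phase 2: communities become
#' nodes, the weight between two new nodes is the summed weight of all links
#' between the two communities, and links inside a community become a
#' self-loop (its diagonal entry holds the full within-community ordered-pair
#' weight, so total weight and modularity are conserved exactly).
#'
#' @param adj sparse symmetric adjacency matrix.
#' @param membership cluster label per node.
#' @return A sparse symmetric adjacency matrix over communities, rownames =
#'   community labels (sorted).
#' @export
aggregate_graph <- function(adj, membership) {
  f <- factor(membership)
  S <- Matrix::sparseMatrix(i = seq_along(membership),
                            j = as.integer(f), x = 1,
                            dims = c(length(membership), nlevels(f)))
  agg <- methods::as(Matrix::crossprod(S, adj %*% S), "CsparseMatrix")
  dimnames(agg) <- list(levels(f), levels(f))
  agg
}

#' Louvain community detection by modularity optimization
#'
#' Two-phase greedy modularity maximization: phase 1 sweeps nodes in a
#' seeded-shuffle order, moving each to the neighbor community with maximal
#' positive gain (Eq. of [modularity_gain()]); phase 2 aggregates communities
#' into super-nodes with summed inter-community weights and within-community
#' self-loops.  The phases repeat until a full pass yields no modularity
#' gain.  Disconnected components are handled naturally (no moves across
#' them); isolated nodes stay singleton clusters.  Final clusters are
#' renumbered 0..K-1 by decreasing size.
#'
#' Greedy local moving can stall in sweep-order-dependent local optima, so
#' the optimization is restarted `n_restarts` times with sub-seeds derived
#' deterministically from `seed`, and the partition with the highest Q is
#' returned (ties go to the earliest restart).
#'
#' @param adj sparse symmetric adjacency matrix with dimnames.
#' @param resolution granularity parameter \eqn{\gamma} (higher = more,
#'   smaller clusters).
#' @param seed integer seed for the sweep order.
#' @param max_passes safety cap on phase-1/phase-2 rounds.
#' @param n_restarts independent seeded restarts of the optimization.
#' @return A list of class `cell_partition`: `membership` (0-based integer
#'   labels named by node id), `modularity`, `resolution`.
#' @export
louvain <- function(adj, resolution = 0.5, seed = 1L, max_passes = 25,
                    n_restarts = 5) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p <- .louvain_once(adj, resolution,
                       seed = as.integer((seed + 7919 * (r - 1)) %%
                                           .Machine$integer.max),
                       max_passes = max_passes)
    if (is.null(best) || p$modularity > best$modularity + 1e-12) best <- p
  }
  best
}

.louvain_once <- function(adj, resolution, seed, max_passes) {
  if (!Matrix::isSymmetric(adj)) stop("adjacency matrix must be symmetric")
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  set.seed(seed)
  flat <- seq_len(n)
  cur <- adj
  q_prev <- -Inf
  for (pass in seq_len(max_passes)) {
    comm <- .louvain_phase1(cur, resolution)
    moved <- length(unique(comm)) < nrow(cur)
    flat <- comm[flat]
    cur <- aggregate_graph(cur, comm)
    flat <- match(as.character(flat), rownames(cur))
    q <- modularity_q(adj, flat, resolution)
    if (!moved || q <= q_prev + 1e-12 || nrow(cur) == 1) break
    q_prev <- q
  }
  # renumber 0..K-1 by decreasing cluster size (ties: first occurrence)
  f <- factor(flat)
  sizes <- table(f)
  new_lab <- integer(nlevels(f))
  new_lab[order(-as.integer(sizes), seq_len(nlevels(f)))] <-
    seq_len(nlevels(f)) - 1L
  membership <- stats::setNames(new_lab[as.integer(f)], ids)
  structure(list(membership = membership,
                 modularity = modularity_q(adj, membership, resolution),
                 resolution = resolution),
            class = "cell_partition")
}
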