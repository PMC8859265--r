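#' Principal component analysis of the scaled expression matrix
#'
#' Computes the top principal components of the gene-scaled data via singular
#' value decomposition of the column-centered cells x genes matrix.  A
#' deterministic sign convention is applied: each loading vector's
#' largest-magnitude entry is made positive (scores flipped accordingly), so
#' results are reproducible across platforms.
#'
#' @param scaled genes x cells scaled matrix from [scale_data()].
#' @param n_pcs number of components to return; truncated to the matrix rank
#'   with a warning if it exceeds it.
#' @return A list of class `pca_result`: `embeddings` (cells x PCs scores),
#'   `loadings` (genes x PCs, orthonormal columns), `explained_variance`
#'   (non-increasing), `total_variance`.
#' @export
run_pca <- function(scaled, n_pcs = 50) {
  X <- t(scaled)                       # cells x genes
  if (n_pcs > min(dim(X)))
    stop("n_pcs exceeds min(genes, cells)")
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  n <- nrow(X)
  ev <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1] * max(dim(X)) * .Machine$double.eps)
  if (n_pcs > rank) {
    warning("n_pcs (", n_pcs, ") exceeds matrix rank (", rank,
            "); truncating")
    n_pcs <- rank
  }
  idx <- seq_len(n_pcs)
  load <- sv$v[, idx, drop = FALSE]
  emb <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_pcs)
  # sign convention: largest-magnitude loading entry positive
  for (k in idx) {
    s <- sign(load[which.max(abs(load[, k])), k])
    if (s < 0) { load[, k] <- -load[, k]; emb[, k] <- -emb[, k] }
  }
  pcn <- paste0("PC", idx)
  dimnames(emb) <- list(colnames(scaled), pcn)
  dimnames(load) <- list(rownames(scaled), pcn)
  structure(list(embeddings = emb, loadings = load,
                 explained_variance = ev[idx], total_variance = sum(ev)),
            class = "pca_result")
}

#' JackStraw significance test for principal components
#'
#' Builds a null distribution of loading magnitudes by repeatedly permuting
#' the cell order of a small random fraction of genes, recomputing PCA, and
#' recording the permuted genes' loadings.  Each gene's per-PC empirical
#' p-value is the fraction of null scores at least as large as its observed
#' loading magnitude; each PC's significance is a one-sided
#' Kolmogorov-Smirnov test of those gene p-values against Uniform(0, 1)
#' (enrichment of small values).
#'
#' @param scaled genes x cells scaled matrix.
#' @param n_pcs number of components to score.
#' @param perm_fraction fraction of genes permuted per replicate (at least
#'   one gene).
#' @param n_replicates number of permutation replicates (a warning is issued
#'   below 10).
#' @param seed integer seed.
#' @return A list of class `jackstraw_result`: `gene_p` (genes x PCs
#'   empirical p-values), `pc_p` (per-PC enrichment p-values),
#'   `n_replicates`, `perm_fraction`.
#' @export
jackstraw <- function(scaled, n_pcs = 20, perm_fraction = 0.01,
                      n_replicates = 100, seed = 1L) {
  G <- nrow(scaled)
  n_perm <- max(1L, round(perm_fraction * G))
  if (n_replicates < 10) warning("fewer than 10 JackStraw replicates")
  obs <- abs(run_pca(scaled, n_pcs)$loadings)
  n_pcs <- ncol(obs)                  # may have been truncated
  set.seed(seed)
  null_scores <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(G, n_perm)
    perm <- scaled
    for (g in idx) perm[g, ] <- perm[g, sample.int(ncol(perm))]
    pl <- suppressWarnings(run_pca(perm, n_pcs)$loadings)
    null_scores[[r]] <- abs(pl[idx, , drop = FALSE])
  }
  null_mat <- do.call(rbind, null_scores)   # (reps * n_perm) x PCs
  gene_p <- matrix(NA_real_, G, n_pcs, dimnames = dimnames(obs))
  for (k in seq_len(n_pcs)) {
    nk <- sort(null_mat[, k])
    ge <- length(nk) - findInterval(obs[, k], nk, left.open = TRUE)
    gene_p[, k] <- (1 + ge) / (1 + length(nk))
  }
  pc_p <- apply(gene_p, 2, function(p)
    suppressWarnings(stats::ks.test(p, "punif",
                                    alternative = "greater")$p.value))
  structure(list(gene_p = gene_p, pc_p = pc_p,
                 n_replicates = n_replicates, perm_fraction = perm_fraction),
            class = "jackstraw_result")
}
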