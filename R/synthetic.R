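#' Configuration for the synthetic count-matrix generator
#'
#' Collects every parameter of the two-part (hurdle) generative model used to
#' simulate droplet-style count matrices with planted cell clusters and
#' planted up-regulated genes.  Detection of gene \eqn{g} in cell \eqn{i} is
#' Bernoulli with \eqn{logit^{-1}} of a per-gene baseline logit (plus a
#' log-odds shift for planted genes in the cell's cluster); conditional on
#' detection, log-expression is Gaussian with a per-gene baseline mean (plus a
#' mean shift for planted genes).  Counts are obtained by exponentiating,
#' scaling by a lognormal per-cell library factor, and rounding; an expressed
#' entry is floored at one count so the observed zero pattern matches the
#' discrete component of the model.
#'
#' @param n_genes,n_cells,n_clusters positive integers.
#' @param cluster_proportions simplex weights of length `n_clusters`
#'   (default equal).
#' @param de_fraction fraction of genes planted as up-regulated per cluster.
#'   Half of each cluster's planted genes are exclusive to it (disjoint
#'   across clusters, giving clean separation); the other half are drawn
#'   from a shared marker pool, so genes recur across clusters -- the
#'   overlap that makes "frequent" markers, mirroring shared expression
#'   programs in real cell types.
#' @param marker_pool_fraction fraction of genes forming the shared pool;
#'   default `de_fraction`, under which an average pool gene is planted in
#'   about half the clusters.
#' @param program_loading,program_detection_loading,program_detection_shift
#'   the shared-pool genes form a co-regulated, highly detected expression
#'   program (emulating the housekeeping/ribosomal programs that dominate
#'   real co-expression networks): each cell carries a latent program
#'   activity \eqn{a_i \sim N(0,1)}; pool genes add
#'   `program_loading * a_i` to their conditional log-expression mean,
#'   `program_detection_loading * a_i` to their detection logit, and
#'   `program_detection_shift` to their baseline detection logit.  Per gene
#'   this is still exactly a hurdle model (the factor folds into the
#'   Gaussian variance); across genes it creates the strong positive
#'   correlations a hub network needs.  Set all three to 0 for independent
#'   genes.
#' @param de_effect_discrete log-odds shift of detection for planted genes.
#' @param de_effect_continuous shift of the conditional log-expression mean.
#' @param baseline_detection_logit length-2 range of per-gene baseline
#'   detection logits.  Detection is coupled to expression the way dropout
#'   behaves in real data: a gene's logit is the range evaluated at its
#'   baseline log-mean's quantile (so lowly expressed genes drop out more),
#'   plus Gaussian jitter of 0.25.
#' @param baseline_mean,baseline_sd mean and residual standard deviation of
#'   the Gaussian log-expression component.
#' @param gene_mean_sd spread (standard deviation across genes) of per-gene
#'   baseline log-means around `baseline_mean`; real expression spans orders
#'   of magnitude, and this spread is what lets variance-stabilized gene
#'   selection separate planted genes from the mean-variance trend.
#' @param libsize_lognormal_params length-2 `(meanlog, sdlog)` of the per-cell
#'   library size factor.
#' @param mito_gene_fraction fraction of genes named with the mitochondrial
#'   prefix `"MT-"`.
#' @param spikein_gene_fraction fraction of genes named with the spike-in
#'   prefix `"ERCC_"`.
#' @param seed integer seed driving all randomness of the generator.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_cells = 500, n_clusters = 4,
                             cluster_proportions = NULL,
                             de_fraction = 0.05,
                             marker_pool_fraction = NULL,
                             de_effect_discrete = 1.5,
                             de_effect_continuous = 0.8,
                             program_loading = 1,
                             program_detection_loading = 1,
                             program_detection_shift = 3,
                             baseline_detection_logit = c(-2, 0.5),
                             baseline_mean = 2, baseline_sd = 0.7,
                             gene_mean_sd = 1,
                             libsize_lognormal_params = c(0, 0.3),
                             mito_gene_fraction = 0.02,
                             spikein_gene_fraction = 0.01,
                             seed = 1L) {
  if (n_genes < 1 || n_cells < 1 || n_clusters < 1)
    stop("n_genes, n_cells and n_clusters must be positive")
  if (n_clusters > n_cells)
    stop("n_clusters must not exceed n_cells")
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have length n_clusters")
  if (any(cluster_proportions < 0) || abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must be non-negative and sum to 1")
  if (is.null(marker_pool_fraction))
    marker_pool_fraction <- de_fraction
  fracs <- c(de_fraction, marker_pool_fraction, mito_gene_fraction,
             spikein_gene_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (length(baseline_detection_logit) != 2)
    stop("baseline_detection_logit must be a length-2 range")
  if (baseline_sd <= 0 || baseline_mean <= 0)
    stop("baseline_mean and baseline_sd must be positive")
  if (gene_mean_sd < 0) stop("gene_mean_sd must be non-negative")
  structure(list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    de_fraction = de_fraction,
    marker_pool_fraction = marker_pool_fraction,
    program_loading = program_loading,
    program_detection_loading = program_detection_loading,
    program_detection_shift = program_detection_shift,
    de_effect_discrete = de_effect_discrete,
    de_effect_continuous = de_effect_continuous,
    baseline_detection_logit = sort(baseline_detection_logit),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    gene_mean_sd = gene_mean_sd,
    libsize_lognormal_params = libsize_lognormal_params,
    mito_gene_fraction = mito_gene_fraction,
    spikein_gene_fraction = spikein_gene_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Largest-remainder apportionment of n cells to cluster proportions.
.apportion <- function(n, prop) {
  raw <- n * prop
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Generate a synthetic count matrix with planted clusters and markers
#'
#' Simulates a genes-by-cells integer count matrix under the hurdle model
#' described in [synthetic_config()], together with a ground-truth object
#' recording cell labels, the planted up-regulated genes of each cluster, the
#' per-gene generative parameters and the per-cell library factors.
#'
#' Cells are ordered by cluster; mitochondrial-named genes are excluded from
#' the planted differentially expressed pool (spike-in-named genes are not, so
#' spike-ins can surface as markers, as they do in real spike-in-containing
#' data sets).
#'
#' @param config a `synthetic_config`.
#' @return A list with `counts` (sparse `dgCMatrix`, genes x cells) and
#'   `truth` (class `synthetic_truth`): `cell_labels` (0-based integer vector
#'   named by barcode), `de_genes` (list mapping cluster label to planted gene
#'   identifiers), `true_params` (data frame of per-gene baseline detection
#'   logit, log-mean, residual variance), `library_factors`, and the effect
#'   sizes used.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  G <- config$n_genes; n <- config$n_cells; K <- config$n_clusters

  n_mito <- round(config$mito_gene_fraction * G)
  n_spike <- round(config$spikein_gene_fraction * G)
  gene_ids <- c(
    sprintf("MT-Synth%04d", seq_len(n_mito)),
    sprintf("ERCC_%05d", seq_len(n_spike)),
    sprintf("Gene%05d", seq_len(G - n_mito - n_spike))
  )
  cell_ids <- sprintf("Cell%05d", seq_len(n))

  sizes <- .apportion(n, config$cluster_proportions)
  labels <- rep(seq_len(K) - 1L, sizes)

  mu0 <- stats::rnorm(G, config$baseline_mean, config$gene_mean_sd)
  rng <- config$baseline_detection_logit
  qt <- if (config$gene_mean_sd > 0)
    stats::pnorm((mu0 - config$baseline_mean) / config$gene_mean_sd)
  else rep(0.5, G)
  b0 <- rng[1] + (rng[2] - rng[1]) * qt + stats::rnorm(G, 0, 0.25)
  sigma <- rep(config$baseline_sd, G)

  eligible <- which(!startsWith(gene_ids, "MT-"))
  n_de <- round(config$de_fraction * G)
  n_shared <- floor(n_de / 2)
  n_excl <- n_de - n_shared
  pool_size <- min(max(n_shared, round(config$marker_pool_fraction * G)),
                   max(0, length(eligible) - K * n_excl))
  marker_pool <- if (pool_size > 0) sort(sample(eligible, pool_size))
                 else integer(0)
  excl_avail <- setdiff(eligible, marker_pool)
  de_genes <- vector("list", K)
  names(de_genes) <- as.character(seq_len(K) - 1L)
  for (k in seq_len(K)) {
    if (n_de == 0) { de_genes[[k]] <- character(0); next }
    own <- sample(excl_avail, min(n_excl, length(excl_avail)))
    excl_avail <- setdiff(excl_avail, own)
    shared <- if (n_shared > 0 && pool_size > 0)
      sample(marker_pool, min(n_shared, pool_size)) else integer(0)
    de_genes[[k]] <- gene_ids[sort(c(own, shared))]
  }

  b0[marker_pool] <- b0[marker_pool] + config$program_detection_shift
  activity <- stats::rnorm(n)

  lib <- stats::rlnorm(n, config$libsize_lognormal_params[1],
                       config$libsize_lognormal_params[2])

  counts <- Matrix::Matrix(0, nrow = G, ncol = n, sparse = TRUE)
  col_start <- cumsum(c(0L, sizes))
  for (k in seq_len(K)) {
    nk <- sizes[k]
    if (nk == 0) next
    cols <- (col_start[k] + 1):(col_start[k] + nk)
    logit0 <- b0
    mu_k <- mu0
    idx <- match(de_genes[[k]], gene_ids)
    logit0[idx] <- logit0[idx] + config$de_effect_discrete
    mu_k[idx] <- mu_k[idx] + config$de_effect_continuous
    logit <- matrix(logit0, G, nk)
    mu <- matrix(mu_k, G, nk)
    if (length(marker_pool) > 0) {
      act <- rep(activity[cols], each = length(marker_pool))
      logit[marker_pool, ] <- logit[marker_pool, ] +
        config$program_detection_loading * act
      mu[marker_pool, ] <- mu[marker_pool, ] + config$program_loading * act
    }
    z <- matrix(stats::rbinom(G * nk, 1L, stats::plogis(logit)), G, nk)
    x <- matrix(stats::rnorm(G * nk, mu, sigma), G, nk)
    cnt <- round(exp(x) * rep(lib[cols], each = G)) * z
    cnt[z == 1L & cnt < 1] <- 1  # expressed entries stay detected
    counts[, cols] <- cnt
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(gene_ids, cell_ids)

  truth <- structure(list(
    cell_labels = stats::setNames(labels, cell_ids),
    de_genes = de_genes,
    true_params = data.frame(
      gene = gene_ids, detect_logit = b0, log_mean = mu0,
      sigma2 = sigma^2 +
        ifelse(seq_len(G) %in% marker_pool, config$program_loading^2, 0),
      is_program = seq_len(G) %in% marker_pool,
      stringsAsFactors = FALSE),
    program_activity = stats::setNames(activity, cell_ids),
    library_factors = stats::setNames(lib, cell_ids),
    de_effect_discrete = config$de_effect_discrete,
    de_effect_continuous = config$de_effect_continuous
  ), class = "synthetic_truth")

  list(counts = counts, truth = truth)
}

#' Generate a planted-partition (stochastic block model) graph
#'
#' Test harness for community detection: nodes are split into blocks and
#' unit-weight edges are sampled independently with probability `p_in` within
#' a block and `p_out` between blocks.
#'
#' @param block_sizes positive integers, one per block.
#' @param p_in,p_out edge probabilities in `[0, 1]` with `p_in > p_out`
#'   (equality allowed for Erdos-Renyi-style null checks).
#' @param seed integer seed.
#' @return A list with `graph` (sparse symmetric adjacency matrix) and
#'   `labels` (0-based block index per node).
#' @export
generate_planted_partition_graph <- function(block_sizes, p_in, p_out,
                                             seed = 1L) {
  if (any(block_sizes <= 0)) stop("block sizes must be positive")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_in < p_out) stop("p_in must be at least p_out")
  set.seed(seed)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes) - 1L, block_sizes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[pairs[, 1]] == labels[pairs[, 2]], p_in, p_out)
  keep <- stats::runif(nrow(pairs)) < p
  i <- pairs[keep, 1]; j <- pairs[keep, 2]
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  list(graph = adj, labels = labels)
}

#' Write a synthetic data set to disk in standard exchange formats
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, 1-based indices,
#' genes as rows), `features.tsv`, `barcodes.tsv`, and the ground truth as
#' `truth_labels.csv` (barcode, cluster) and `truth_de.csv` (cluster, gene).
#' The matrix round-trips bit-exactly through [read_counts()].
#'
#' @param counts genes x cells integer matrix with dimnames.
#' @param truth a `synthetic_truth`, or `NULL` to write the matrix only.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(counts, truth, dir) {
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("cannot write an empty matrix (zero genes or cells)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell identifiers")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  trip <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  con <- file(mtx, "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), length(trip@x)),
             con)
  ord <- order(trip@j, trip@i)
  writeLines(sprintf("%d %d %d", trip@i[ord] + 1L, trip@j[ord] + 1L,
                     as.integer(trip@x[ord])), con)
  close(con)
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  paths <- c(mtx, file.path(dir, c("features.tsv", "barcodes.tsv")))
  if (!is.null(truth)) {
    lab <- file.path(dir, "truth_labels.csv")
    utils::write.csv(data.frame(barcode = names(truth$cell_labels),
                                cluster = unname(truth$cell_labels)),
                     lab, row.names = FALSE, quote = FALSE)
    de <- file.path(dir, "truth_de.csv")
    de_df <- do.call(rbind, lapply(names(truth$de_genes), function(k) {
      if (length(truth$de_genes[[k]]) == 0) return(NULL)
      data.frame(cluster = k, gene = truth$de_genes[[k]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(de_df))
      de_df <- data.frame(cluster = character(0), gene = character(0))
    utils::write.csv(de_df, de, row.names = FALSE, quote = FALSE)
    paths <- c(paths, lab, de)
  }
  invisible(paths)
}
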