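#' Pipeline configuration with the workflow's default parameters
#'
#' Collects every stage parameter of the end-to-end analysis.  Defaults are
#' the workflow's standard settings: pre-filter at 3 cells / 200 features, QC
#' retention at 200--2500 features and at most 5% mitochondrial counts,
#' scale factor \eqn{10^4}, 2000 highly variable genes, 50 computed PCs of
#' which 10 feed clustering, k = 20 neighbors, SNN pruning at 1/15,
#' resolution 0.5, fold-change and detection pre-filters at 0.25,
#' correlation threshold 0.5, and 20 hub genes.
#'
#' @param min_cells,min_features,max_features,max_mito QC thresholds.
#' @param scale_factor,log_base normalization parameters.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs computed principal components.
#' @param n_pcs_use components used for the neighbor graph.
#' @param jackstraw_reps,jackstraw_frac JackStraw replicates and permuted
#'   gene fraction (report-only; does not gate `n_pcs_use`).
#' @param knn_k,prune neighbor count and SNN pruning threshold.
#' @param resolution Louvain resolution.
#' @param logfc_min,min_pct marker pre-filter thresholds.
#' @param corr_threshold Spearman edge threshold.
#' @param top_n_hubs number of hub genes reported.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cells = 3, min_features = 200,
                            max_features = 2500, max_mito = 5,
                            scale_factor = 1e4, log_base = "natural",
                            n_hvg = 2000, n_pcs = 50, n_pcs_use = 10,
                            jackstraw_reps = 100, jackstraw_frac = 0.01,
                            knn_k = 20, prune = 1 / 15, resolution = 0.5,
                            logfc_min = 0.25, min_pct = 0.25,
                            corr_threshold = 0.5, top_n_hubs = 20,
                            seed = 1L) {
  cfg <- list(min_cells = min_cells, min_features = min_features,
              max_features = max_features, max_mito = max_mito,
              scale_factor = scale_factor, log_base = log_base,
              n_hvg = n_hvg, n_pcs = n_pcs, n_pcs_use = n_pcs_use,
              jackstraw_reps = jackstraw_reps,
              jackstraw_frac = jackstraw_frac,
              knn_k = knn_k, prune = prune, resolution = resolution,
              logfc_min = logfc_min, min_pct = min_pct,
              corr_threshold = corr_threshold, top_n_hubs = top_n_hubs,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg a configuration list.
#' @return Invisibly `TRUE`; errors describe the offending field.
#' @export
validate_pipeline_config <- function(cfg) {
  if (cfg$max_features < cfg$min_features)
    stop("max_features must be at least min_features")
  if (cfg$min_cells < 0 || cfg$min_features < 0)
    stop("filter thresholds must be non-negative")
  if (cfg$max_mito < 0 || cfg$max_mito > 100)
    stop("max_mito must lie in [0, 100]")
  if (cfg$scale_factor <= 0) stop("scale_factor must be positive")
  if (cfg$n_pcs_use > cfg$n_pcs)
    stop("n_pcs_use cannot exceed n_pcs")
  if (cfg$resolution <= 0) stop("resolution must be positive")
  if (cfg$prune < 0 || cfg$prune > 1) stop("prune must lie in [0, 1]")
  for (f in c("logfc_min", "min_pct", "corr_threshold"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For the reader, a `pipeline_config`; the writer returns the path
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg), precision = 12), path)
  invisible(path)
}

# Deterministic per-stage seeds derived from the global one (kept below
# 2^31 so they remain valid R integers).
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gene/cell pre-filter, QC metrics and cell filter,
#' log-normalization, highly-variable-gene selection, per-gene scaling, PCA,
#' JackStraw (reported only; the number of PCs used downstream is the
#' explicit `n_pcs_use` parameter), KNN/SNN graph, Louvain clustering,
#' one-vs-rest hurdle marker detection, frequent-marker counting, Spearman
#' network construction, centrality metrics and hub ranking.  Identical
#' configuration and seed give identical results.
#'
#' @param input a count matrix (genes x cells with dimnames), a path readable
#'   by [read_counts()], or a `synthetic_config` (the data are then
#'   generated, and planted-marker recall against the ground truth is added
#'   to the manifest).
#' @param config a `pipeline_config`.
#' @param output_dir optional directory; when given, every stage table is
#'   written as CSV/TSV (and the network as GraphML).
#' @param run_jackstraw set `FALSE` to skip the (report-only) JackStraw
#'   stage.
#' @return A list with `manifest` (configuration snapshot, per-stage
#'   dimensions, seed, package version, timestamp) and every stage result:
#'   `counts`, `qc`, `normalized`, `hvg`, `pca`, `jackstraw`, `graph`,
#'   `partition`, `markers`, `frequent`, `network`, `centrality`, `hubs`,
#'   and `truth` for synthetic input.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         output_dir = NULL, run_jackstraw = TRUE) {
  validate_pipeline_config(config)
  truth <- NULL
  if (inherits(input, "synthetic_config")) {
    sim <- generate_counts(input)
    counts <- sim$counts
    truth <- sim$truth
  } else if (is.character(input)) {
    counts <- read_counts(input)
  } else {
    counts <- input
  }
  dims <- list(input = dim(counts))
  message("input: ", nrow(counts), " genes x ", ncol(counts), " cells")

  counts <- prefilter(counts, config$min_cells, config$min_features)
  dims$prefilter <- dim(counts)
  message("prefilter: ", nrow(counts), " genes x ", ncol(counts), " cells")

  qc <- compute_qc_metrics(counts)
  counts <- qc_filter_cells(counts, qc, config$min_features,
                            config$max_features, config$max_mito)
  dims$qc <- dim(counts)
  message("QC filter: ", ncol(counts), " cells retained")

  normalized <- log_normalize(counts, config$scale_factor, config$log_base)
  counts <- counts[, colnames(normalized$values), drop = FALSE]

  trend <- fit_mean_variance_trend(counts)
  hvg <- select_hvg(counts, trend, n_top = min(config$n_hvg, nrow(counts)))
  hvg_genes <- hvg$gene[hvg$selected]
  message("HVG: ", length(hvg_genes), " genes selected")

  scaled <- scale_data(normalized, hvg_genes)
  n_pcs <- min(config$n_pcs, dim(scaled) - 1)
  pca <- run_pca(scaled, n_pcs)
  js <- if (run_jackstraw)
    jackstraw(scaled, n_pcs = min(config$n_pcs_use, n_pcs),
              perm_fraction = config$jackstraw_frac,
              n_replicates = config$jackstraw_reps,
              seed = .stage_seed(config$seed, 1L)) else NULL

  emb <- pca$embeddings[, seq_len(min(config$n_pcs_use, n_pcs)),
                        drop = FALSE]
  sets <- knn_sets(emb, k = config$knn_k)
  graph <- snn_jaccard(sets, prune_below = config$prune)
  dims$graph_edges <- length(graph@x) / 2
  message("SNN graph: ", dims$graph_edges, " edges")

  partition <- louvain(graph, resolution = config$resolution,
                       seed = .stage_seed(config$seed, 2L))
  dims$n_clusters <- length(unique(partition$membership))
  message("Louvain: ", dims$n_clusters, " clusters, Q = ",
          round(partition$modularity, 4))

  markers <- find_all_cluster_markers(normalized, partition,
                                      logfc_min = config$logfc_min,
                                      min_pct = config$min_pct)
  dims$n_marker_records <- nrow(markers)
  dims$n_unique_markers <- length(unique(markers$gene))
  freq <- frequent_markers(markers)
  freq_genes <- freq$gene[freq$is_frequent]
  dims$n_frequent_markers <- length(freq_genes)
  message("markers: ", dims$n_marker_records, " records, ",
          dims$n_unique_markers, " unique, ",
          dims$n_frequent_markers, " frequent")

  network <- centrality <- hubs <- NULL
  if (length(freq_genes) >= 2) {
    network <- spearman_network(normalized, freq_genes,
                                threshold = config$corr_threshold)
    dims$network_edges <- nrow(network$edges)
    centrality <- centrality_metrics(network)
    hubs <- top_hubs(centrality, config$top_n_hubs)
  }

  manifest <- list(config = unclass(config), dims = dims,
                   seed = config$seed,
                   version = as.character(utils::packageVersion("scFreqMark")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(truth)) {
    sig <- markers[markers$p_adj_bonferroni <= 0.05, ]
    manifest$planted_marker_recall <- marker_recall(sig, truth, partition)
  }

  result <- list(manifest = manifest, counts = counts, qc = qc,
                 normalized = normalized, hvg = hvg, pca = pca,
                 jackstraw = js, graph = graph, partition = partition,
                 markers = markers, frequent = freq, network = network,
                 centrality = centrality, hubs = hubs, truth = truth)
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

# Best-matching of found clusters to planted ones by cell overlap, then the
# fraction of planted genes recovered as significant markers of the matched
# cluster.
marker_recall <- function(sig_markers, truth, partition) {
  found <- partition$membership[names(truth$cell_labels)]
  recalls <- vapply(names(truth$de_genes), function(k) {
    planted <- truth$de_genes[[k]]
    if (length(planted) == 0) return(NA_real_)
    cells_k <- names(truth$cell_labels)[truth$cell_labels == as.integer(k)]
    match_cl <- names(which.max(table(found[cells_k])))
    hit <- sig_markers$gene[sig_markers$cluster == match_cl]
    mean(planted %in% hit)
  }, 0)
  mean(recalls, na.rm = TRUE)
}

#' Write every stage output of a pipeline run to a directory
#'
#' @param result list returned by [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE, quote = FALSE)
  w(result$qc, "qc_metrics.csv")
  w(result$hvg, "hvg_table.csv")
  utils::write.csv(data.frame(cell = rownames(result$pca$embeddings),
                              result$pca$embeddings, check.names = FALSE),
                   file.path(dir, "pca_embeddings.csv"), row.names = FALSE)
  if (!is.null(result$jackstraw))
    w(data.frame(pc = names(result$jackstraw$pc_p),
                 p_value = unname(result$jackstraw$pc_p)),
      "jackstraw_pc_pvalues.csv")
  utils::write.table(graph_edge_list(result$graph),
                     file.path(dir, "snn_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  w(data.frame(barcode = names(result$partition$membership),
               cluster = unname(result$partition$membership)),
    "clusters.csv")
  w(result$markers, "markers.csv")
  w(as.data.frame(result$frequent), "frequent_markers.csv")
  if (!is.null(result$network)) {
    utils::write.table(result$network$edges,
                       file.path(dir, "network_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_network_graphml(result$network,
                          file.path(dir, "network.graphml"))
    w(as.data.frame(result$centrality), "centrality.csv")
    w(result$hubs, "top_hubs.csv")
  }
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
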