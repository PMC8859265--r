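# Row means/variances for dense or sparse genes x cells matrices.
.row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowSums(m^2)
  v <- (sq - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  list(mean = mu, var = v)
}

#' Fit the mean-variance trend for variance-stabilized gene selection
#'
#' Fits a local polynomial regression (degree 2, loess) of
#' \eqn{\log_{10}(variance)} on \eqn{\log_{10}(mean)} across genes with
#' positive mean and variance of their raw counts.  The fitted (regularized)
#' variance -- not the raw one -- is what standardization uses, so genes are
#' judged against the variance expected at their own mean.
#'
#' @param counts genes x cells raw count matrix.
#' @param span loess span on the log10-mean axis.
#' @return A function mapping raw-count means to expected variances (raw
#'   scale).  Means outside the fitted range are clamped to its boundary.
#' @export
fit_mean_variance_trend <- function(counts, span = 0.3) {
  st <- .row_stats(counts)
  use <- st$mean > 0 & st$var > 0
  if (sum(use) < 10)
    stop("need at least 10 genes with positive mean and variance")
  lx <- log10(st$mean[use]); ly <- log10(st$var[use])
  fit <- stats::loess(ly ~ lx, span = span, degree = 2,
                      family = "gaussian")
  rng <- range(lx)
  function(mu) {
    lmu <- pmin(pmax(log10(pmax(mu, .Machine$double.eps)), rng[1]), rng[2])
    10^stats::predict(fit, data.frame(lx = lmu))
  }
}

#' Select highly variable genes by standardized variance
#'
#' Standardizes each raw count as \eqn{y_{ij} = (p_{ij} - \bar p_i)/\sigma_i},
#' where \eqn{\sigma_i} is the expected standard deviation from the
#' mean-variance trend, clips values above \eqn{\sqrt M} (\eqn{M} = number of
#' cells) to damp technical outliers, and ranks genes by the variance of the
#' clipped values across cells.  The top `n_top` genes are flagged; ties are
#' broken by gene order in the matrix.
#'
#' @param counts genes x cells raw count matrix.
#' @param trend trend function from [fit_mean_variance_trend()] (fitted on
#'   this matrix), or `NULL` to fit one here.
#' @param n_top number of genes to flag.
#' @param clip_max clipping ceiling; default \eqn{\sqrt M}.
#' @return A data frame (class `hvg_stats`) with one row per gene: `gene`,
#'   `mean`, `variance`, `expected_variance`, `standardized_variance`, `rank`,
#'   `selected`.
#' @export
select_hvg <- function(counts, trend = NULL, n_top = 2000, clip_max = NULL) {
  G <- nrow(counts); M <- ncol(counts)
  if (n_top > G) stop("n_top exceeds the number of genes")
  if (is.null(trend)) trend <- fit_mean_variance_trend(counts)
  if (is.null(clip_max)) clip_max <- sqrt(M)
  st <- .row_stats(counts)
  exp_var <- as.numeric(trend(st$mean))
  sd_i <- sqrt(pmax(exp_var, 0))

  m <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  nz_by_gene <- split(m@x, factor(m@i + 1L, levels = seq_len(G)))
  std_var <- numeric(G)
  for (g in seq_len(G)) {
    if (sd_i[g] <= 0 || st$var[g] == 0) { std_var[g] <- 0; next }
    y0 <- min((0 - st$mean[g]) / sd_i[g], clip_max)
    ynz <- pmin((nz_by_gene[[g]] - st$mean[g]) / sd_i[g], clip_max)
    n0 <- M - length(ynz)
    s1 <- sum(ynz) + n0 * y0
    s2 <- sum(ynz^2) + n0 * y0^2
    std_var[g] <- max((s2 - s1^2 / M) / (M - 1), 0)
  }
  rk <- order(-std_var, seq_len(G))
  rank_of <- integer(G); rank_of[rk] <- seq_len(G)
  out <- data.frame(gene = rownames(counts), mean = st$mean,
                    variance = st$var, expected_variance = exp_var,
                    standardized_variance = std_var, rank = rank_of,
                    selected = rank_of <= n_top,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hvg_stats", "data.frame")
  out
}

#' Scale (z-score) normalized expression per gene
#'
#' Centers and scales each gene of the log-normalized matrix to mean 0,
#' standard deviation 1 across cells, so no gene dominates downstream PCA by
#' raw expression level.  Scores above `cap` are clipped to `cap` to bound
#' outlier leverage; genes with zero standard deviation become all-zero rows.
#'
#' @param normalized a `normalized_matrix` (or a plain genes x cells matrix
#'   of normalized values).
#' @param genes character vector of genes to keep (e.g. the selected HVGs),
#'   or `NULL` for all.
#' @param cap upper clip on z-scores.
#' @return A dense genes x cells matrix of scaled expression.
#' @export
scale_data <- function(normalized, genes = NULL, cap = 10) {
  vals <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing) > 0)
      stop("genes not present in the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  x <- as.matrix(vals)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  pmin(z, cap)
}
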