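# Two-part (hurdle) differential expression: logistic regression on the
# detection indicator plus a Gaussian model on positive log-expression, with
# the cellular detection rate as a covariate, tested by likelihood ratio.

#' Cellular detection rate
#'
#' Fraction of genes detected (expression > 0) in each cell:
#' \eqn{CDR_i = \frac{1}{N} \sum_g z_{ig}} with \eqn{N} the total number of
#' genes.  Depends only on the zero pattern of the matrix.
#'
#' @param y genes x cells expression matrix (normalized or raw).
#' @return Numeric vector of per-cell detection rates in `[0, 1]`.
#' @export
compute_cdr <- function(y) {
  vals <- if (inherits(y, "normalized_matrix")) y$values else y
  if (nrow(vals) == 0) stop("matrix has no genes")
  stats::setNames(as.numeric(Matrix::colMeans(vals > 0)), colnames(vals))
}

# Ridge-penalized logistic IRLS.  The tiny default ridge keeps separated
# fits finite; the reported log-likelihood is the unpenalized one.
.logistic_fit <- function(X, z, ridge = 1e-8, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, z - mu)) - ridge * beta
    H <- crossprod(X * wt, X) + diag(ridge, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  ll <- sum(z * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  list(beta = beta, loglik = ll)
}

# Gaussian least-squares fit with MLE residual variance.
.gaussian_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  s2 <- sum(fit$residuals^2) / n
  s2 <- max(s2, 1e-12)
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  list(beta = fit$coefficients, sigma2 = s2, loglik = ll)
}

#' Fit the two-part hurdle model for one gene
#'
#' The discrete part is a maximum-likelihood logistic regression of the
#' detection indicator \eqn{z = (y > 0)} on the design, over all cells (a
#' tiny L2 ridge keeps separated fits finite).  The continuous part is a
#' Gaussian least-squares fit of \eqn{y} on the design over the cells with
#' \eqn{z = 1}; it is dropped (contributing nothing to the likelihood ratio)
#' when fewer than `ncol(X) + 2` cells are positive.  A rank-deficient
#' design triggers a warning naming the dependent columns; the ridge still
#' yields a well-defined fit.
#'
#' @param y expression values for one gene across cells.
#' @param X design matrix (cells x covariates), e.g. intercept, group
#'   indicator, centered CDR.
#' @param ridge L2 penalty on the logistic coefficients.
#' @return A list of class `hurdle_fit`: `beta_d`, `beta_c`, `sigma2`,
#'   `loglik_d`, `loglik_c`, `n_positive`, `has_continuous`, `df_d`, `df_c`.
#' @export
fit_hurdle <- function(y, X, ridge = 1e-8) {
  if (length(y) != nrow(X)) stop("y and design have different lengths")
  if (nrow(X) < 3) stop("need at least 3 cells")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    if (is.null(dep)) dep <- as.character(qrX$pivot[-seq_len(qrX$rank)])
    warning("design is rank-deficient; dependent column(s): ",
            paste(dep, collapse = ", "))
  }
  z <- as.numeric(y > 0)
  disc <- .logistic_fit(X, z, ridge = ridge)
  pos <- which(z == 1)
  has_cont <- length(pos) >= ncol(X) + 2
  if (has_cont) {
    cont <- .gaussian_fit(X[pos, , drop = FALSE], y[pos])
  } else {
    cont <- list(beta = rep(NA_real_, ncol(X)), sigma2 = NA_real_,
                 loglik = 0)
  }
  structure(list(beta_d = disc$beta, beta_c = cont$beta,
                 sigma2 = cont$sigma2,
                 loglik_d = disc$loglik, loglik_c = cont$loglik,
                 n_positive = length(pos), has_continuous = has_cont,
                 df_d = ncol(X), df_c = if (has_cont) ncol(X) else 0L),
            class = "hurdle_fit")
}

#' Hurdle likelihood-ratio test
#'
#' The statistic is twice the log-likelihood difference between the full and
#' null fits, summed over the discrete and continuous parts; the continuous
#' part contributes only when present in both fits.  Degrees of freedom are
#' the number of dropped design columns per contributing part.  Small
#' negative statistics (within numerical tolerance) are clamped to zero;
#' larger ones indicate a fit failure and raise an error.
#'
#' @param full,null `hurdle_fit` objects on nested designs over the same
#'   cells.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
hurdle_lrt <- function(full, null) {
  df_per_part <- full$df_d - null$df_d
  if (df_per_part <= 0) stop("null design must be nested in the full design")
  stat_d <- 2 * (full$loglik_d - null$loglik_d)
  use_cont <- full$has_continuous && null$has_continuous
  stat_c <- if (use_cont) 2 * (full$loglik_c - null$loglik_c) else 0
  for (s in c(stat_d, stat_c))
    if (s < -1e-8) stop("negative likelihood-ratio statistic (", s,
                        "): fit failure")
  stat <- max(stat_d, 0) + max(stat_c, 0)
  df <- df_per_part * (1L + as.integer(use_cont))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Log2 fold change and detection fractions between two cell groups
#'
#' The detection fraction `pct` of each group is the fraction of its cells
#' with expression > 0.  The fold change de-logs the normalized values:
#' \deqn{log2FC = \log_2 \frac{\mathrm{mean}_1(e^y - 1) + 1}
#'                            {\mathrm{mean}_2(e^y - 1) + 1}}
#' i.e. group means on the (pseudo-counted) expression scale, which avoids
#' the small-value distortion of differencing log means.
#'
#' @param normalized a `normalized_matrix` or genes x cells matrix of
#'   log-normalized values (natural log).
#' @param group1,group2 cell identifiers (or column indices) of the
#'   experimental and control groups.
#' @param genes genes to evaluate (default all).
#' @return Data frame with `gene`, `log2fc`, `pct_1`, `pct_2`.
#' @export
log2fc_and_pct <- function(normalized, group1, group2, genes = NULL) {
  vals <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be non-empty")
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  v1 <- vals[, group1, drop = FALSE]
  v2 <- vals[, group2, drop = FALSE]
  pct1 <- as.numeric(Matrix::rowMeans(v1 > 0))
  pct2 <- as.numeric(Matrix::rowMeans(v2 > 0))
  m1 <- as.numeric(Matrix::rowSums(expm1(v1))) / ncol(v1)
  m2 <- as.numeric(Matrix::rowSums(expm1(v2))) / ncol(v2)
  data.frame(gene = rownames(vals), log2fc = log2((m1 + 1) / (m2 + 1)),
             pct_1 = pct1, pct_2 = pct2, stringsAsFactors = FALSE)
}

#' One-vs-rest hurdle differential expression for every cluster
#'
#' For each cluster (the experimental group) against all remaining cells
#' (the control group): genes are pre-filtered by detection fraction
#' (`max(pct_1, pct_2) >= min_pct`) and fold change (`log2fc >= logfc_min`,
#' or `|log2fc|` when `only_upregulated = FALSE`) before testing; survivors
#' are tested by the hurdle likelihood ratio with design
#' (intercept, group, centered CDR).  Bonferroni adjustment multiplies each
#' p-value by the total number of genes in the data set (not just those
#' tested); Benjamini-Hochberg values over the tested genes of each cluster
#' are reported alongside.  Clusters with fewer than 3 cells are skipped with
#' a warning.
#'
#' @param normalized a `normalized_matrix` or genes x cells matrix.
#' @param partition a `cell_partition` or a vector of cluster labels named
#'   by cell.
#' @param logfc_min fold-change pre-filter threshold.
#' @param min_pct detection-fraction pre-filter threshold.
#' @param only_upregulated keep only up-regulated genes (one-sided filter).
#' @param p_adj_max optional ceiling on the Bonferroni-adjusted p-value of
#'   returned records (`NULL` keeps all tested genes).
#' @return Data frame of marker records sorted by cluster then p-value:
#'   `cluster`, `gene`, `p_value`, `p_adj_bonferroni`, `p_adj_bh`, `log2fc`,
#'   `pct_1`, `pct_2`.
#' @export
find_all_cluster_markers <- function(normalized, partition,
                                     logfc_min = 0.25, min_pct = 0.25,
                                     only_upregulated = TRUE,
                                     p_adj_max = NULL) {
  vals <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  labels <- if (inherits(partition, "cell_partition"))
    partition$membership else partition
  if (is.null(names(labels))) names(labels) <- colnames(vals)
  labels <- labels[colnames(vals)]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  n_genes_total <- nrow(vals)
  cdr <- compute_cdr(vals)
  cdr_c <- cdr - mean(cdr)
  dense <- as.matrix(vals)
  records <- list()
  for (cl in clusters) {
    in_cl <- which(labels == cl)
    if (length(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    out_cl <- which(labels != cl)
    fc <- log2fc_and_pct(vals, in_cl, out_cl)
    pass_fc <- if (only_upregulated) fc$log2fc >= logfc_min
               else abs(fc$log2fc) >= logfc_min
    test_idx <- which(pmax(fc$pct_1, fc$pct_2) >= min_pct & pass_fc)
    if (length(test_idx) == 0) next
    group <- as.numeric(seq_len(ncol(vals)) %in% in_cl)
    X_full <- cbind(intercept = 1, group = group, cdr = cdr_c)
    X_null <- X_full[, c("intercept", "cdr"), drop = FALSE]
    pvals <- vapply(test_idx, function(g) {
      yg <- dense[g, ]
      hurdle_lrt(fit_hurdle(yg, X_full), fit_hurdle(yg, X_null))$p_value
    }, 0)
    rec <- data.frame(cluster = cl, gene = fc$gene[test_idx],
                      p_value = pvals,
                      p_adj_bonferroni = pmin(1, pvals * n_genes_total),
                      p_adj_bh = stats::p.adjust(pvals, "BH"),
                      log2fc = fc$log2fc[test_idx],
                      pct_1 = fc$pct_1[test_idx],
                      pct_2 = fc$pct_2[test_idx],
                      stringsAsFactors = FALSE)
    records[[as.character(cl)]] <- rec[order(rec$p_value, rec$gene), ]
  }
  out <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cluster = character(0), gene = character(0),
                      p_value = numeric(0), p_adj_bonferroni = numeric(0),
                      p_adj_bh = numeric(0), log2fc = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0))
  if (!is.null(p_adj_max)) out <- out[out$p_adj_bonferroni <= p_adj_max, ]
  rownames(out) <- NULL
  out
}
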