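test_that("mean-variance trend recovers a Poisson-like relationship", {
  set.seed(1)
  G <- 400; n <- 300
  mu <- 10^runif(G, -0.5, 1.5)
  m <- matrix(rpois(G * n, mu), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:n)))
  trend <- fit_mean_variance_trend(m)
  mids <- mu > 1 & mu < 20
  rel_err <- abs(trend(mu[mids]) - mu[mids]) / mu[mids]
  expect_lt(stats::median(rel_err), 0.1)
  expect_true(all(trend(rowMeans(m)) > 0))
})

test_that("degenerate inputs to the trend fit are rejected", {
  m <- matrix(3, nrow = 1, ncol = 10,
              dimnames = list("g1", paste0("c", 1:10)))
  expect_error(fit_mean_variance_trend(m), "at least 10")
  m2 <- matrix(5, nrow = 20, ncol = 10,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  expect_error(fit_mean_variance_trend(m2), "at least 10")  # all constant
})

test_that("standardized variances match hand arithmetic including clipping", {
  # 4 genes x 6 cells, hand-fixed trend sigma_i^2 = mean_i
  m <- matrix(c(1, 1, 1, 1, 1, 1,     # constant
                0, 0, 0, 0, 0, 12,    # extreme outlier -> clipping
                0, 1, 2, 3, 4, 5,
                2, 2, 2, 2, 2, 8), nrow = 4, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC", "gD"), paste0("c", 1:6)))
  trend <- function(mu) mu          # expected variance = mean
  hv <- select_hvg(m, trend, n_top = 2)
  M <- 6; clip <- sqrt(M)
  hand <- apply(m, 1, function(x) {
    y <- pmin((x - mean(x)) / sqrt(mean(x)), clip)
    stats::var(y)
  })
  expect_equal(hv$standardized_variance, unname(hand), tolerance = 1e-12)
  # gB's outlier y = (12-2)/sqrt(2) = 7.07 was clipped at sqrt(6)
  expect_gt((12 - 2) / sqrt(2), clip)
  # constant gene has zero standardized variance and is never selected
  expect_equal(hv$standardized_variance[1], 0)
  expect_false(hv$selected[1])
  expect_equal(sum(hv$selected), 2)
})

test_that("selection returns exactly n_top genes and errors when impossible", {
  cfg <- synthetic_config(n_genes = 120, n_cells = 50, seed = 6)
  m <- generate_counts(cfg)$counts
  hv <- select_hvg(m, n_top = 30)
  expect_equal(sum(hv$selected), 30)
  expect_error(select_hvg(m, n_top = 121), "exceeds")
})

test_that("standardized variance is invariant to cell relabeling", {
  cfg <- synthetic_config(n_genes = 100, n_cells = 40, seed = 9)
  m <- as.matrix(generate_counts(cfg)$counts)
  trend <- fit_mean_variance_trend(m)
  hv1 <- select_hvg(m, trend, 10)
  perm <- sample(ncol(m))
  hv2 <- select_hvg(m[, perm], trend, 10)
  expect_equal(hv1$standardized_variance, hv2$standardized_variance)
})

test_that("planted high-variance genes are recovered at high rate", {
  # Poisson baseline plus negative-binomial overdispersed planted genes:
  # the planted genes carry severalfold extra variance at their mean
  set.seed(21)
  G <- 400; n <- 250
  mu <- 10^runif(G, -0.3, 1.3)
  m <- matrix(rpois(G * n, mu), G, n)
  planted <- sample(G, 40)
  m[planted, ] <- matrix(rnbinom(40 * n, mu = mu[planted], size = 0.7),
                         40, n)
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:n))
  hv <- select_hvg(m, n_top = 80)
  expect_gt(mean(sprintf("g%03d", planted) %in% hv$gene[hv$selected]), 0.9)
  # integration: the generator's co-regulated program genes (extra
  # log-scale variance loading^2) are strongly enriched in the HVG set
  cfg <- synthetic_config(n_genes = 500, n_cells = 200, n_clusters = 2,
                          de_fraction = 0.05, program_loading = 1.5,
                          seed = 21)
  sim <- generate_counts(cfg)
  hv2 <- select_hvg(sim$counts, n_top = 100)
  prog <- sim$truth$true_params$gene[sim$truth$true_params$is_program]
  expect_gt(mean(prog %in% hv2$gene[hv2$selected]), 0.75)
})

test_that("scaling gives zero-mean unit-sd rows and handles constants", {
  set.seed(2)
  m <- matrix(rnorm(9, 5), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  z <- scale_data(m)
  hand <- t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(z, hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  # constant gene -> all-zero row, no NaN
  m2 <- rbind(m, gC = c(4, 4, 4))
  z2 <- scale_data(m2)
  expect_equal(unname(z2["gC", ]), c(0, 0, 0))
  expect_false(anyNA(z2))
})

test_that("z-scores are capped at +10", {
  x <- c(rep(0, 400), 1000)
  m <- rbind(g1 = x, g2 = rev(x))
  colnames(m) <- paste0("c", seq_along(x))
  z <- scale_data(m)
  expect_equal(max(z), 10)
})

test_that("PCA matches a dense eigendecomposition oracle on a toy matrix", {
  set.seed(3)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  p <- run_pca(m, n_pcs = 3)
  X <- sweep(t(m), 2, colMeans(t(m)))
  ev <- eigen(cov(X))$values
  expect_equal(p$explained_variance, ev[1:3], tolerance = 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # explained variances sum to total variance at full rank
  p_full <- run_pca(m, n_pcs = 3)
  expect_equal(sum(run_pca(m, 3)$explained_variance[1:3]), sum(ev[1:3]),
               tolerance = 1e-10)
})

test_that("a rank-2 matrix has (near) zero variance beyond PC2", {
  set.seed(4)
  u <- matrix(rnorm(20), 10, 2)
  v <- matrix(rnorm(16), 8, 2)
  m <- u %*% t(v)                       # genes x cells, rank 2
  dimnames(m) <- list(paste0("g", 1:10), paste0("c", 1:8))
  expect_warning(p <- run_pca(m, n_pcs = 7), "rank")
  expect_lte(length(p$explained_variance), 2)   # truncated to true rank
  ev_full <- svd(sweep(t(m), 2, rowMeans(m)))$d^2
  expect_lt(ev_full[3] / ev_full[1], 1e-20)
})

test_that("embeddings times loadings reconstructs the centered input", {
  set.seed(5)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:4)))
  p <- run_pca(m, n_pcs = 3)            # full rank for 4 cells
  X <- sweep(t(m), 2, colMeans(t(m)))
  expect_equal(p$embeddings %*% t(p$loadings), X, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the PCA sign convention is deterministic", {
  set.seed(6)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  p <- run_pca(m, 4)
  for (k in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
})

test_that("jackstraw is deterministic and flags planted structure", {
  set.seed(7)
  G <- 120; n <- 50
  noise <- matrix(rnorm(G * n), G, n)
  # two strong planted components
  f1 <- rnorm(n); f2 <- rnorm(n)
  signal <- outer(rnorm(G, sd = c(rep(2, 30), rep(0, G - 30))), f1) +
    outer(rnorm(G, sd = c(rep(0, G - 30), rep(2, 30))), f2)
  m <- noise + signal
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("c%02d", 1:n))
  scaled <- scale_data(m)
  js1 <- jackstraw(scaled, n_pcs = 6, perm_fraction = 0.05,
                   n_replicates = 40, seed = 11)
  js2 <- jackstraw(scaled, n_pcs = 6, perm_fraction = 0.05,
                   n_replicates = 40, seed = 11)
  expect_identical(js1$gene_p, js2$gene_p)
  expect_lt(max(js1$pc_p[1:2]), 0.01)
  expect_gt(min(js1$pc_p[5:6]), 0.01)
})

test_that("jackstraw p-values are roughly uniform on pure noise", {
  # aggregate over independent noise matrices: under uniformity the
  # expected number of PCs flagged at alpha = 0.05 is 0.75 of 15
  flagged <- 0
  for (s in 1:3) {
    set.seed(8 + s)
    m <- matrix(rnorm(100 * 40), 100, 40,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%02d", 1:40)))
    js <- jackstraw(scale_data(m), n_pcs = 5, perm_fraction = 0.05,
                    n_replicates = 40, seed = 12)
    flagged <- flagged + sum(js$pc_p < 0.05)
    expect_true(all(js$gene_p > 0 & js$gene_p <= 1))
  }
  expect_lte(flagged, 3)
})

test_that("too few replicates warns", {
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  expect_warning(jackstraw(scale_data(m), 2, 0.1, n_replicates = 5, seed = 1),
                 "replicates")
})
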