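test_that("Aitchison distance has the clr closed form and scale invariance", {
  x <- rbind(c(1, 1), c(1, exp(2)))
  rownames(x) <- c("S1", "S2")
  d <- aitchison_distance(clr_transform(x))
  expect_equal(as.numeric(d), sqrt(2), tolerance = 1e-12)
  # identical samples at distance zero
  same <- clr_transform(rbind(a = c(2, 3, 5), b = c(2, 3, 5)))
  expect_equal(as.numeric(aitchison_distance(same)), 0)
  # rescaling one sample's counts changes nothing
  y <- rbind(c(2, 3, 5), c(1, 9, 4), c(3, 3, 3))
  y2 <- y; y2[2, ] <- y2[2, ] * 10
  expect_equal(as.matrix(aitchison_distance(clr_transform(y))),
               as.matrix(aitchison_distance(clr_transform(y2))))
  expect_error(aitchison_distance(matrix(c(1, NA), 1)), "NA")
})

test_that("PCoA recovers Euclidean configurations and equals clr PCA", {
  set.seed(21)
  pts <- matrix(rnorm(20), 10, 2)
  ord <- pcoa(dist(pts))
  pr <- procrustes_r(ord$coordinates, pts, n_perm = 99)
  expect_equal(pr$r, 1, tolerance = 1e-8)

  # three equidistant samples: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ord3 <- pcoa(d3)
  expect_equal(length(ord3$eigenvalues), 2)
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-10)

  # PCoA of Aitchison distances == PCA of clr coordinates up to sign
  set.seed(22)
  comp <- matrix(rexp(15 * 6) + 0.05, 15, 6)
  clr <- clr_transform(comp)
  ordA <- pcoa(aitchison_distance(clr))
  pca <- prcomp(clr, center = TRUE, scale. = FALSE)
  k <- ncol(ordA$coordinates)
  for (j in seq_len(k)) {
    diff1 <- max(abs(ordA$coordinates[, j] - pca$x[, j]))
    diff2 <- max(abs(ordA$coordinates[, j] + pca$x[, j]))
    expect_lt(min(diff1, diff2), 1e-8)
  }
  # coordinates reproduce the distances exactly
  expect_equal(as.matrix(dist(ordA$coordinates)),
               as.matrix(aitchison_distance(clr)), tolerance = 1e-8)
})

test_that("ANOSIM R matches the Clarke brute-force oracle", {
  set.seed(23)
  for (r in 1:8) {
    x <- matrix(rnorm(14 * 3), 14, 3)
    g <- factor(rep(c("a", "b"), each = 7))
    d <- dist(x)
    fit <- anosim_test(d, g, n_perm = 99, seed = r)
    expect_equal(fit$R, oracle_anosim_R(d, g), tolerance = 1e-10)
    expect_gte(fit$R, -1); expect_lte(fit$R, 1)
    # rank-based: monotone transform of the distances leaves R unchanged
    fit2 <- anosim_test(d^2, g, n_perm = 99, seed = r)
    expect_equal(fit2$R, fit$R, tolerance = 1e-10)
  }
  # two tight, far-separated clusters: R = 1
  far <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 50, 0.01), 5))
  gf <- factor(rep(c("a", "b"), each = 5))
  expect_equal(anosim_test(dist(far), gf, n_perm = 99)$R, 1)
  expect_error(anosim_test(dist(far), factor(c("a", rep("b", 9)))), "at least 2")
})

test_that("PERMANOVA detects a planted shift and BH adjusts pairwise tests", {
  set.seed(24)
  x <- matrix(rnorm(30 * 5), 30, 5)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  x[g == "c", ] <- x[g == "c", ] + 4
  d <- dist(x)
  fit <- permanova(d, g, n_perm = 999, seed = 1)
  expect_gt(fit$pseudo_F, 0)
  expect_lte(fit$p_value, 0.001)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))
  # BH arithmetic
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  expect_warning(permanova(d, g, n_perm = 50, seed = 1), "99")
})

test_that("Procrustes r is 1 for rotated/scaled copies and symmetric", {
  set.seed(25)
  A <- matrix(rnorm(24), 12, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  B <- 3.2 * A %*% R + 5
  pr <- procrustes_r(A, B, n_perm = 99)
  expect_equal(pr$r, 1, tolerance = 1e-8)
  expect_lte(pr$p_value, 0.05)
  r_ab <- procrustes_r(A, B, n_perm = 0)$r
  r_ba <- procrustes_r(B, A, n_perm = 0)$r
  expect_equal(r_ab, r_ba, tolerance = 1e-10)
  expect_error(procrustes_r(A[1:2, ], B[1:2, ]), "3 samples")
})

test_that("RV coefficient matches the double-sum oracle", {
  set.seed(26)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(rv_coefficient(X, X, n_perm = 0)$rv, 1, tolerance = 1e-12)
  for (r in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(40), 10, 4)
    expect_equal(rv_coefficient(X, Y, n_perm = 0)$rv, oracle_rv(X, Y),
                 tolerance = 1e-10)
  }
  # exactly zero cross-covariance
  X0 <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  Y0 <- cbind(c(1, -1, -1, 1))
  expect_equal(rv_coefficient(X0, Y0, n_perm = 0)$rv, 0, tolerance = 1e-12)
  expect_error(rv_coefficient(matrix(0, 4, 2), Y0, n_perm = 0),
               "zero-variance")
  # permutation p small when Y is a copy of X
  pv <- rv_coefficient(X, X + matrix(rnorm(30, 0, 0.01), 10, 3),
                       n_perm = 199, seed = 1)$p_value
  expect_lte(pv, 0.01)
})

test_that("RV-matrix PCA reconstructs K and handles degenerate cases", {
  # identity K: projections are scaled axis vectors, all pairs sqrt(2) apart
  K <- diag(6)
  p <- rv_matrix_pca(K)
  dists <- dist(p$projections)
  expect_equal(as.numeric(dists), rep(sqrt(2), 15), tolerance = 1e-10)

  # all-ones 3x3: eigenvalues (3,0,0), PC1 entries of magnitude 1
  K1 <- matrix(1, 3, 3)
  p1 <- rv_matrix_pca(K1)
  expect_equal(p1$eigenvalues, c(3, 0, 0), tolerance = 1e-12)
  expect_equal(abs(p1$projections[, 1]), rep(1, 3), tolerance = 1e-10)

  # random PSD K: U L^2 U' reconstruction
  set.seed(27)
  for (r in 1:5) {
    M <- matrix(rnorm(36), 6, 6)
    K <- crossprod(M)
    K <- K / max(abs(K))
    p <- rv_matrix_pca(K)
    rec <- p$projections %*% t(p$projections)
    # projections are U L, so (U L)(U L)' = U L^2 U' = K
    expect_lt(max(abs(rec - K)), 1e-8)
  }
  expect_error(rv_matrix_pca(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(rv_matrix_pca(rbind(c(0, 1), c(1, 0))), "indefinite")
})

test_that("rv_matrix builds a unit-diagonal symmetric matrix in [0,1]", {
  set.seed(28)
  configs <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  names(configs) <- paste0("cfg", 1:4)
  K <- rv_matrix(configs)
  expect_equal(diag(K), rep(1, 4), ignore_attr = TRUE)
  expect_equal(K, t(K))
  expect_true(all(K >= 0 & K <= 1))
})
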