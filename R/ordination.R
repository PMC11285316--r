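#' Aitchison distance matrix
#'
#' Euclidean distance between clr-transformed compositions: the
#' beta-diversity metric of compositional data analysis. Scale-invariant by
#' construction (rescaling a sample's counts does not move it).
#'
#' @param clr_matrix samples x taxa matrix of clr coordinates (rows summing
#'   to zero), e.g. from [clr_transform()].
#' @return a `dist` object over samples.
#' @export
aitchison_distance <- function(clr_matrix) {
  if (anyNA(clr_matrix)) stop("NA entries in clr matrix")
  stats::dist(clr_matrix)
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix: eigendecomposition of the
#' double-centered squared distances, coordinates sorted by eigenvalue, with
#' percent explained variance per axis. Aitchison distances are Euclidean,
#' so negative eigenvalues beyond numerical noise indicate an input error
#' and are rejected.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param tol tolerance for negative eigenvalues (default 1e-8, relative to
#'   the leading eigenvalue).
#' @return object of class `pcoa_result`: list with `coordinates`,
#'   `eigenvalues`, `explained` (percent per axis).
#' @export
pcoa <- function(d, tol = 1e-8) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sc <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- sc$eig
  lead <- max(eig)
  if (any(eig < -tol * max(lead, 1)))
    stop("substantially negative eigenvalues: the distances are not Euclidean")
  pos <- which(eig > tol * max(lead, 1))
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = eig[pos],
                 explained = 100 * eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes; PCo1 %.1f%%, PCo2 %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$explained[1], if (length(x$explained) > 1) x$explained[2] else NA))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group distances,
#' `R in [-1, 1]`, with a permutation p-value. Wraps [vegan::anosim()];
#' the permutation p uses the (b+1)/(m+1) convention (observed statistic
#' included in the null set).
#'
#' @param d distance matrix (`dist` or symmetric matrix).
#' @param groups factor of group labels (every group of size >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `R` and `p_value`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), groups, permutations = n_perm)
  list(R = unname(fit$statistic), p_value = fit$signif)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' between/within partition of squared distances, p-value by label
#' permutation. Wraps [vegan::adonis2()].
#'
#' @inheritParams anosim_test
#' @return list with `pseudo_F`, `p_value`, `R2`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (n_perm < 99) warning("fewer than 99 permutations limits p resolution")
  set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(stats::as.dist(d) ~ groups, data = df,
                        permutations = n_perm)
  list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1], R2 = fit$R2[1])
}

#' Pairwise PERMANOVA post-hoc tests with BH correction
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values with
#' the Benjamini-Hochberg procedure.
#'
#' @inheritParams anosim_test
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  dm <- as.matrix(d)
  levs <- levels(droplevels(groups))
  pairs <- utils::combn(levs, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    pseudo_F = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    keep <- groups %in% pairs[, k]
    fit <- permanova(stats::as.dist(dm[keep, keep]),
                     droplevels(groups[keep]), n_perm = n_perm,
                     seed = seed + k)
    res$pseudo_F[k] <- fit$pseudo_F
    res$p_value[k] <- fit$p_value
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Symmetric Procrustes correlation between two ordinations
#'
#' Optimal translation, scaling and rotation of one configuration onto the
#' other; `r = sqrt(1 - m2)` where `m2` is the minimized residual sum of
#' squares relative to the total. Uses all axes with positive eigenvalues,
#' truncated to the smaller configuration; permutation p-value by row
#' shuffling (via [vegan::protest()]).
#'
#' @param a,b `pcoa_result` objects (or coordinate matrices) over the same
#'   samples in the same order.
#' @param n_perm permutations for the significance test (default 999).
#' @param seed integer seed.
#' @return list with `r`, `m2`, `p_value`.
#' @export
procrustes_r <- function(a, b, n_perm = 999, seed = 1) {
  A <- if (inherits(a, "pcoa_result")) a$coordinates else as.matrix(a)
  B <- if (inherits(b, "pcoa_result")) b$coordinates else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("configurations must share samples")
  if (nrow(A) < 3) stop("need at least 3 samples")
  k <- min(ncol(A), ncol(B))
  A <- A[, seq_len(k), drop = FALSE]
  B <- B[, seq_len(k), drop = FALSE]
  set.seed(seed)
  fit <- vegan::protest(A, B, permutations = n_perm)
  list(r = sqrt(1 - fit$ss), m2 = fit$ss, p_value = fit$signif)
}

#' RV coefficient of co-inertia between two sample-matched matrices
#'
#' The multivariate generalization of squared correlation:
#' `RV = trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2))` on
#' column-centered matrices, in \[0, 1\]. The permutation test shuffles the
#' rows of one matrix; p-values follow the (b+1)/(m+1) convention.
#'
#' @param x,y matrices with the same rows (samples); columns are centered
#'   internally.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed.
#' @return list with `rv` and `p_value` (`NA` when `n_perm = 0`).
#' @export
rv_coefficient <- function(x, y, n_perm = 999, seed = 1) {
  X <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) stop("matrices must share samples")
  rv_of <- function(X, Y) {
    Sxy <- crossprod(X, Y)
    Sxx <- crossprod(X)
    Syy <- crossprod(Y)
    den <- sqrt(sum(Sxx^2) * sum(Syy^2))
    if (den == 0) stop("zero-variance configuration")
    sum(Sxy^2) / den
  }
  rv <- rv_of(X, Y)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    null <- replicate(n_perm, rv_of(X[sample(nrow(X)), , drop = FALSE], Y))
    p <- (sum(null >= rv) + 1) / (n_perm + 1)
  }
  list(rv = rv, p_value = p)
}

#' Pairwise RV matrix across platform/rank datasets
#'
#' Builds the symmetric matrix `K` of pairwise RV coefficients between a
#' set of sample-matched configurations (typically the PCoA projections of
#' 2 platforms x 3 ranks = 6 datasets). The diagonal is 1 by definition and
#' off-diagonal entries are clipped to \[0, 1\].
#'
#' @param configs named list of sample-matched coordinate matrices or
#'   `pcoa_result` objects.
#' @return symmetric RV matrix with unit diagonal.
#' @export
rv_matrix <- function(configs) {
  mats <- lapply(configs, function(a)
    if (inherits(a, "pcoa_result")) a$coordinates else as.matrix(a))
  p <- length(mats)
  K <- diag(1, p)
  dimnames(K) <- list(names(configs), names(configs))
  for (i in seq_len(p)) for (j in seq_len(p)) if (j > i) {
    K[i, j] <- K[j, i] <-
      min(1, max(0, rv_coefficient(mats[[i]], mats[[j]], n_perm = 0)$rv))
  }
  K
}

#' Principal component projection of an RV matrix
#'
#' Eigendecomposition `K = U L^2 U'` of the (positive semidefinite) RV
#' matrix, eigenvalues sorted descending with small negatives clipped to
#' zero; the dataset projections are `U L`. The leading axes summarize which
#' datasets resemble each other.
#'
#' @param K symmetric RV matrix (e.g. from [rv_matrix()]).
#' @param tol tolerance for negative eigenvalues (default 1e-8).
#' @return list with `projections` (datasets x axes, `U L`), `eigenvalues`
#'   (`L^2`), `explained` (percent per axis).
#' @export
rv_matrix_pca <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-10) stop("K must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1)))
    stop("K is substantially indefinite")
  lam2 <- pmax(e$values, 0)
  proj <- e$vectors %*% diag(sqrt(lam2), length(lam2))
  rownames(proj) <- rownames(K)
  colnames(proj) <- paste0("PC", seq_along(lam2))
  list(projections = proj, eigenvalues = lam2,
       explained = 100 * lam2 / sum(lam2))
}
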