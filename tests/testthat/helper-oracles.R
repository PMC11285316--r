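# Independent brute-force oracles, deliberately naive implementations.

oracle_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# average ranks by explicit tie groups, then the Pearson product-moment
# formula written out longhand
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank(x), oracle_rank(y))
}

# Kendall tau-b by full pair enumeration with tie corrections
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

oracle_chao1 <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# Clarke's ANOSIM R: rank all pairwise distances (average ties), contrast
# mean between-group and within-group ranks, divide by n(n-1)/4
oracle_anosim_R <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  dv <- dm[lower.tri(dm)]
  same <- outer(groups, groups, "==")[lower.tri(dm)]
  r <- oracle_rank(dv)
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

# RV by explicit double sums of cross-covariance products
oracle_rv <- function(x, y) {
  X <- scale(x, scale = FALSE); Y <- scale(y, scale = FALSE)
  num <- 0
  for (a in seq_len(ncol(X))) for (b in seq_len(ncol(Y)))
    num <- num + sum(X[, a] * Y[, b])^2
  dx <- 0
  for (a in seq_len(ncol(X))) for (b in seq_len(ncol(X)))
    dx <- dx + sum(X[, a] * X[, b])^2
  dy <- 0
  for (a in seq_len(ncol(Y))) for (b in seq_len(ncol(Y)))
    dy <- dy + sum(Y[, a] * Y[, b])^2
  num / sqrt(dx * dy)
}

# exact Wilcoxon rank-sum p (two-sided) by full enumeration of group
# assignments; feasible for n <= 8 per group
oracle_wilcoxon_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- oracle_rank(x)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(x), n1)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  # R's two-sided convention: double the smaller tail, capped at 1
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}
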