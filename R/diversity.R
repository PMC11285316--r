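#' Rarefy a count vector to a fixed depth
#'
#' Draws `depth` reads without replacement from the sample (a multivariate
#' hypergeometric draw, taken taxon by taxon with [stats::rhyper()] so that
#' study-scale depths of millions of reads need no expanded read vector).
#' Reproducible under a fixed seed.
#'
#' @param sample_counts integer vector of taxon counts.
#' @param depth target depth, at most `sum(sample_counts)`.
#' @param seed optional integer seed.
#' @return integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(sample_counts, depth, seed = NULL) {
  x <- sample_counts
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  total <- sum(x)
  if (depth > total) stop("depth exceeds the sample's total count")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(length(x))
  remaining <- total
  left <- depth
  for (j in seq_along(x)) {
    if (left == 0) break
    # draw how many of the remaining `left` reads hit taxon j
    k <- stats::rhyper(1, m = x[j], n = remaining - x[j], k = left)
    out[j] <- k
    left <- left - k
    remaining <- remaining - x[j]
  }
  names(out) <- names(x)
  out
}

#' Shannon diversity (nats)
#'
#' `H = -sum(p_j log p_j)` over positive proportions, via
#' [vegan::diversity()].
#'
#' @param counts non-negative vector (or samples x taxa matrix) of counts.
#' @return Shannon index in nats (vector if a matrix is given).
#' @export
shannon <- function(counts) {
  if (is.matrix(counts)) {
    if (any(rowSums(counts) <= 0)) stop("all-zero sample")
    return(vegan::diversity(counts, index = "shannon"))
  }
  if (sum(counts) <= 0) stop("all-zero sample")
  unname(vegan::diversity(matrix(counts, nrow = 1), index = "shannon"))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and
#' `F2` are the singleton and doubleton counts; this form is defined even
#' when no doubletons are present. The classic form
#' `S_obs + F1^2 / (2 F2)` is available with `bias_corrected = FALSE`.
#' Requires raw integer counts (singletons are meaningless after
#' normalization).
#'
#' @param counts non-negative integer vector.
#' @param bias_corrected use the bias-corrected form (default `TRUE`).
#' @return estimated species richness (`>= S_obs`).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("Chao1 requires raw integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2
}

#' Alpha diversity per sample, with per-platform rarefaction
#'
#' Shannon diversity is computed after rarefying every sample to the
#' platform's minimum depth (so read-depth differences do not inflate
#' evenness estimates); Chao1 is computed from the raw counts because its
#' correction uses the rare tail directly. A single seeded rarefaction draw
#' per sample is used by default; `n_draws > 1` averages Shannon over
#' repeated draws.
#'
#' @param table an `abundance_table` of raw integer counts.
#' @param depth rarefaction depth; defaults to the minimum sample total.
#' @param seed integer seed for the rarefaction draws.
#' @param n_draws number of rarefaction draws averaged (default 1).
#' @return data.frame `sample_id, platform, rank, shannon, chao1,
#'   depth_used`.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1, n_draws = 1) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$counts
  if (is.null(depth)) depth <- min(rowSums(x))
  set.seed(seed)
  sh <- numeric(nrow(x))
  ch <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    draws <- replicate(n_draws, shannon(rarefy_counts(x[i, ], depth)))
    sh[i] <- mean(draws)
    ch[i] <- chao1(x[i, ])
  }
  data.frame(sample_id = rownames(x), platform = table$platform,
             rank = table$rank, shannon = sh, chao1 = ch,
             depth_used = depth, stringsAsFactors = FALSE)
}

#' Compare alpha diversity between the two platforms
#'
#' Tests the platform distributions with a two-sided Wilcoxon rank-sum test
#' (unpaired, matching the headline analysis; a paired signed-rank variant is
#' available) and measures the per-sample association with Spearman's rho
#' (default) plus Pearson's r, overall and within each diagnosis stratum.
#'
#' @param alpha_sg,alpha_16s data.frames from [alpha_diversity()] for the
#'   same samples.
#' @param metric `"shannon"` or `"chao1"`.
#' @param diagnosis optional factor of per-sample diagnosis labels (aligned
#'   with `alpha_sg$sample_id`) for stratified correlations.
#' @param paired use the paired signed-rank test instead (default `FALSE`).
#' @return list with `wilcoxon_p`, `spearman`, `pearson` and per-stratum
#'   correlations.
#' @export
compare_alpha <- function(alpha_sg, alpha_16s, metric = c("shannon", "chao1"),
                          diagnosis = NULL, paired = FALSE) {
  metric <- match.arg(metric)
  i <- match(alpha_sg$sample_id, alpha_16s$sample_id)
  if (anyNA(i)) stop("sample sets differ between platforms")
  a <- alpha_sg[[metric]]
  b <- alpha_16s[[metric]][i]
  if (length(a) < 3) stop("need at least 3 paired samples")
  # exact p when feasible (small, tie-free); normal approximation otherwise
  w <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  pe <- suppressWarnings(stats::cor.test(a, b, method = "pearson"))
  strata <- NULL
  if (!is.null(diagnosis)) {
    strata <- lapply(split(seq_along(a), diagnosis), function(ix) {
      if (length(ix) < 3) return(c(spearman = NA, pearson = NA))
      suppressWarnings(
        c(spearman = stats::cor(a[ix], b[ix], method = "spearman"),
          pearson = stats::cor(a[ix], b[ix])))
    })
  }
  list(metric = metric, wilcoxon_p = w$p.value,
       spearman = unname(sp$estimate), spearman_p = sp$p.value,
       pearson = unname(pe$estimate), pearson_p = pe$p.value,
       by_diagnosis = strata)
}

#' Per-sample sparsity profile and group tests
#'
#' The fraction of zero entries per sample, compared between platforms with
#' a Wilcoxon rank-sum test and across diagnosis groups (within each
#' platform) with Kruskal-Wallis tests. With two platforms, three ranks and
#' filtered/unfiltered variants the analysis runs 12 group tests, so a
#' Bonferroni guide level of 0.05/12 is reported alongside.
#'
#' @param paired a `paired_study`.
#' @param rank taxonomic rank at which to profile.
#' @return list with per-sample zero fractions, `wilcoxon_p` between
#'   platforms, per-platform Kruskal-Wallis p-values and `bonferroni_alpha`.
#' @export
sparsity_profile <- function(paired, rank = "species") {
  tabs <- study_at_rank(paired, rank)
  z_sg <- rowMeans(tabs$shotgun$counts == 0)
  z_16 <- rowMeans(tabs$x16s$counts == 0)
  diag <- paired$metadata$diagnosis
  kw <- function(z) {
    if (nlevels(droplevels(diag)) < 2) return(NA_real_)
    stats::kruskal.test(z, diag)$p.value
  }
  list(rank = rank, zeros_shotgun = z_sg, zeros_16s = z_16,
       wilcoxon_p = stats::wilcox.test(z_sg, z_16, exact = FALSE)$p.value,
       kruskal_p = c(shotgun = kw(z_sg), `16S` = kw(z_16)),
       bonferroni_alpha = 0.05 / 12)
}
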