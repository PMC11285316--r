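#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two categorical sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' computed from the marginal products. Returns `NA` when `p_e = 1` (both
#' sequences constant in the same category), where the statistic is
#' undefined.
#'
#' @param a,b equal-length vectors (any categories; compared as factors over
#'   the union of observed levels).
#' @return the kappa statistic in \[-1, 1\], or `NA` if undefined.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 observations")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Normal-approximation interval using the large-sample standard error
#' `sqrt(p_o (1 - p_o) / n) / (1 - p_e)`.
#'
#' @param a,b equal-length category vectors.
#' @param conf_level confidence level (default 0.95).
#' @return list with `kappa`, `se`, `lower`, `upper`.
#' @export
cohens_kappa_ci <- function(a, b, conf_level = 0.95) {
  k <- cohens_kappa(a, b)
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(as.character(a), lev), factor(as.character(b), lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (is.na(k)) return(list(kappa = NA_real_, se = NA_real_,
                            lower = NA_real_, upper = NA_real_))
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = k, se = se,
       lower = max(-1, k - z * se), upper = min(1, k + z * se))
}

# Detected = non-zero raw count in at least one sample. Overlap is a
# detection question, so it is computed before zero replacement.
detected_taxa <- function(table) {
  taxa_names(table)[colSums(table$counts > 0) > 0]
}

# Match 16S taxon labels against shotgun labels; with any_candidate, a
# slash-taxon matches if any of its candidate species is a shotgun name.
match_16s <- function(labels_16s, labels_sg, any_candidate = FALSE) {
  if (!any_candidate) return(labels_16s %in% labels_sg)
  vapply(candidate_sets(labels_16s),
         function(cs) any(cs %in% labels_sg), logical(1))
}

# Aggregate both platform tables of a paired study to a rank.
study_at_rank <- function(paired, rank) {
  list(shotgun = aggregate_rank(paired$shotgun, rank),
       x16s = aggregate_rank(paired$x16s, rank))
}

#' Global taxonomic overlap between platforms
#'
#' Counts the taxa detected (non-zero in at least one sample) by each
#' platform at a rank, the taxa detected by both, and the shared fraction
#' relative to each platform. Both tables should be harmonized and stripped
#' of unnamed taxa first.
#'
#' @param paired a `paired_study` (tables at species rank or already at
#'   `rank`).
#' @param rank taxonomic rank for the comparison.
#' @param any_candidate if `TRUE`, a slash-named 16S taxon counts as shared
#'   when any of its candidate species is detected by shotgun; default is
#'   exact label matching after harmonization.
#' @return an object of class `overlap_summary`.
#' @export
global_overlap <- function(paired, rank = "species", any_candidate = FALSE) {
  tabs <- study_at_rank(paired, rank)
  t16 <- detected_taxa(tabs$x16s)
  tsg <- detected_taxa(tabs$shotgun)
  shared16 <- t16[match_16s(t16, tsg, any_candidate)]
  n_shared <- length(shared16)
  structure(list(
    rank = rank,
    n_16s = length(t16), n_shotgun = length(tsg), n_shared = n_shared,
    n_16s_only = length(t16) - n_shared,
    n_shotgun_only = length(tsg) -
      if (any_candidate) n_shared else length(intersect(tsg, t16)),
    shared_over_16s = 100 * n_shared / max(1, length(t16)),
    shared_over_shotgun = 100 * n_shared / max(1, length(tsg)),
    shared_taxa = shared16), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "overlap at %s: 16S %d | shotgun %d | shared %d (%.1f%% of 16S, %.1f%% of shotgun)\n",
    x$rank, x$n_16s, x$n_shotgun, x$n_shared,
    x$shared_over_16s, x$shared_over_shotgun))
  invisible(x)
}

#' Per-sample taxonomic and abundance agreement
#'
#' For every sample: the number of taxa detected by both platforms in that
#' sample, the percentage relative to the sample's detected 16S and shotgun
#' taxa, the Spearman correlation of counts over the sample's shared taxa,
#' and Cohen's kappa over the sample's shared taxa using median-binarized
#' abundances (taxon medians computed on the full per-platform table, then
#' restricted to the sample). Samples where a statistic is undefined (for
#' example no shared taxa, or constant binarizations) carry `NA` and are
#' excluded from the reported summaries.
#'
#' @inheritParams global_overlap
#' @return data.frame of class `per_sample_overlap` with one row per sample
#'   and attribute `"summary"` holding median/quartile/range summaries.
#' @export
per_sample_overlap <- function(paired, rank = "species") {
  tabs <- study_at_rank(paired, rank)
  sg <- tabs$shotgun$counts
  s16 <- tabs$x16s$counts
  common <- intersect(colnames(sg), colnames(s16))
  bin_sg <- median_binarize(sg)
  bin_16 <- median_binarize(s16)
  ids <- rownames(sg)
  res <- data.frame(sample_id = ids, n_shared = NA_integer_,
                    pct_of_16s = NA_real_, pct_of_shotgun = NA_real_,
                    spearman = NA_real_, kappa = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s <- ids[i]
    det_sg <- colnames(sg)[sg[s, ] > 0]
    det_16 <- colnames(s16)[s16[s, ] > 0]
    shared <- intersect(intersect(det_sg, det_16), common)
    res$n_shared[i] <- length(shared)
    res$pct_of_16s[i] <- if (length(det_16)) 100 * length(shared) / length(det_16) else NA
    res$pct_of_shotgun[i] <- if (length(det_sg)) 100 * length(shared) / length(det_sg) else NA
    if (length(shared) >= 3) {
      res$spearman[i] <- suppressWarnings(
        stats::cor(sg[s, shared], s16[s, shared], method = "spearman"))
    }
    if (length(shared) >= 2) {
      res$kappa[i] <- cohens_kappa(bin_sg[s, shared], bin_16[s, shared])
    }
  }
  summ <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(median = NA, q1 = NA, q3 = NA, min = NA, max = NA))
    c(median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75)),
      min = min(v), max = max(v))
  }
  attr(res, "summary") <- list(
    rank = rank,
    n_shared = summ(res$n_shared), pct_of_16s = summ(res$pct_of_16s),
    pct_of_shotgun = summ(res$pct_of_shotgun),
    spearman = summ(res$spearman), kappa = summ(res$kappa),
    n_undefined = c(spearman = sum(is.na(res$spearman)),
                    kappa = sum(is.na(res$kappa))))
  class(res) <- c("per_sample_overlap", "data.frame")
  res
}

#' Cross-platform correlation of average abundances
#'
#' Spearman correlation between the two platforms' compositional centres
#' (closed geometric means after zero replacement) over the taxa shared by
#' both platforms at a rank.
#'
#' @inheritParams global_overlap
#' @return list with `rho`, `p_value`, `n_shared` and the two centre
#'   vectors over shared taxa.
#' @export
abundance_correlation <- function(paired, rank = "species") {
  tabs <- study_at_rank(paired, rank)
  shared <- intersect(detected_taxa(tabs$shotgun), detected_taxa(tabs$x16s))
  if (length(shared) < 3)
    stop("fewer than 3 shared taxa at rank ", rank)
  c_sg <- closed_geometric_mean(replace_zeros(tabs$shotgun))[shared]
  c_16 <- closed_geometric_mean(replace_zeros(tabs$x16s))[shared]
  ct <- suppressWarnings(
    stats::cor.test(c_sg, c_16, method = "spearman", exact = FALSE))
  list(rank = rank, rho = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared), centre_shotgun = c_sg, centre_16s = c_16)
}

#' Most prevalent taxa by compositional centre
#'
#' Orders taxa by their closed geometric mean abundance (descending, ties
#' broken alphabetically) and returns the first `k`.
#'
#' @param table an `abundance_table` with strictly positive entries (after
#'   [replace_zeros()]); raw tables are zero-replaced on the fly.
#' @param k number of taxa to return (default 50).
#' @return character vector of taxon labels, most abundant first.
#' @export
top_prevalent <- function(table, k = 50) {
  if (inherits(table, "abundance_table") && any(table$counts == 0))
    table <- replace_zeros(table)
  centre <- closed_geometric_mean(table)
  ord <- order(-centre, names(centre))
  if (k > length(centre)) {
    warning("k exceeds the number of taxa; returning all")
    k <- length(centre)
  }
  names(centre)[ord][seq_len(k)]
}
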