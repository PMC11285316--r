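#' Genome-length normalization of shotgun counts
#'
#' Shotgun read counts scale with genome length: a large genome yields more
#' reads per cell. Dividing each taxon's counts by its genome length removes
#' this bias; each sample is then rescaled back to its original library size
#' so the table stays on a read-like scale (downstream analyses are
#' compositional, so only the proportions matter).
#'
#' @param table a shotgun `abundance_table` with `genome_lengths`.
#' @return the normalized `abundance_table`.
#' @export
genome_length_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$platform != "shotgun")
    stop("genome-length normalization applies to shotgun tables")
  gl <- table$genome_lengths
  if (is.null(gl))
    stop("genome lengths are missing")
  bad <- !(colnames(table$counts) %in% names(gl)) |
    is.na(gl[colnames(table$counts)]) | gl[colnames(table$counts)] <= 0
  if (any(bad))
    stop("missing or non-positive genome length for: ",
         paste(utils::head(colnames(table$counts)[bad], 5), collapse = ", "))
  gl <- gl[colnames(table$counts)]
  totals <- rowSums(table$counts)
  norm <- sweep(table$counts, 2, gl, `/`)
  norm_tot <- rowSums(norm)
  scale <- ifelse(norm_tot > 0, totals / norm_tot, 1)
  out <- table
  out$counts <- norm * scale
  out
}

#' Filter specification for rare-taxon removal
#'
#' @param min_sample_fraction minimum fraction of samples in which a taxon
#'   must reach `min_rel_abundance` (default 0.05, i.e. 5\% of samples).
#' @param min_rel_abundance within-sample relative abundance threshold
#'   (default 0.001, i.e. 0.1\%).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_sample_fraction = 0.05, min_rel_abundance = 0.001) {
  stopifnot(min_sample_fraction >= 0, min_sample_fraction < 1,
            min_rel_abundance >= 0, min_rel_abundance < 1)
  structure(list(min_sample_fraction = min_sample_fraction,
                 min_rel_abundance = min_rel_abundance),
            class = "filter_spec")
}

#' Prevalence/abundance filter
#'
#' Retains a taxon iff its within-sample relative abundance reaches
#' `min_rel_abundance` in at least `ceiling(min_sample_fraction * n)` of the
#' `n` samples. Rounding up keeps the "at least 5\% of samples" guarantee
#' when `n` is not divisible.
#'
#' @param table an `abundance_table`.
#' @param spec a `filter_spec`.
#' @return the filtered `abundance_table`.
#' @export
prevalence_filter <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "abundance_table"))
  totals <- rowSums(table$counts)
  rel <- table$counts / ifelse(totals > 0, totals, 1)
  n_hit <- colSums(rel >= spec$min_rel_abundance & table$counts > 0)
  need <- ceiling(spec$min_sample_fraction * n_samples(table))
  keep <- which(n_hit >= need)
  if (length(keep) == 0L)
    warning("all taxa removed by the prevalence filter")
  replace_table(table, table$counts[, keep, drop = FALSE],
                table$lineage[keep, , drop = FALSE])
}

#' Bayesian-multiplicative zero replacement (square-root prior)
#'
#' Microbiome count tables contain many zeros that break log-ratio analysis.
#' Each sample's composition is treated as a multinomial with a uniform
#' Dirichlet prior whose total strength is the square root of the sample's
#' depth; posterior expectation imputes each zero as
#' `sqrt(n) / (D * (n + sqrt(n)))`, capped below the sample's smallest
#' observed proportion (at `cap_frac` times it) so imputed values always sit
#' under the detection limit. Non-zero parts are multiplicatively rescaled,
#' preserving their ratios exactly, and each row is returned closed (summing
#' to one).
#'
#' @param table an `abundance_table` (raw or length-normalized counts).
#' @param cap_frac cap on imputed values as a fraction of the sample's
#'   minimum observed proportion (default 0.65).
#' @return an `abundance_table` of strictly positive closed compositions.
#' @export
replace_zeros <- function(table, cap_frac = 0.65) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$counts
  if (any(rowSums(x) <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  D <- ncol(x)
  out <- matrix(0, nrow(x), D, dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    n <- sum(xi)
    p <- xi / n
    zero <- xi == 0
    if (!any(zero)) {
      out[i, ] <- p
      next
    }
    s <- sqrt(n)
    imp <- s / (D * (n + s))
    min_obs <- min(p[!zero])
    imp <- min(imp, cap_frac * min_obs)
    out[i, zero] <- imp
    out[i, !zero] <- p[!zero] * (1 - imp * sum(zero))
  }
  res <- table
  res$counts <- out
  res
}

#' Centered log-ratio transform
#'
#' Maps each strictly positive composition row to
#' `log(x_ij / geometric_mean(row i))`; rows of the result sum to zero, and
#' the transform is invariant to per-sample rescaling.
#'
#' @param table an `abundance_table` with strictly positive entries (run
#'   [replace_zeros()] first), or a positive matrix.
#' @return samples x taxa matrix of clr coordinates.
#' @export
clr_transform <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (any(x <= 0))
    stop("clr requires strictly positive entries; run replace_zeros() first")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Median binarization of abundances
#'
#' For every taxon, samples with counts strictly greater than that taxon's
#' median (across all samples of the platform) are coded 1, the rest 0. Ties
#' with the median are 0, so a constant taxon is all-zero.
#'
#' @param table an `abundance_table` or matrix (samples x taxa).
#' @return integer 0/1 matrix of the same shape.
#' @export
median_binarize <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  med <- apply(x, 2, stats::median)
  storage.mode(x) <- "double"
  out <- sweep(x, 2, med, `>`) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Closed geometric mean (compositional centre)
#'
#' The compositional "average" community: the per-taxon geometric mean
#' across samples, rescaled (closed) to sum to one.
#'
#' @param table an `abundance_table` or matrix with strictly positive
#'   entries.
#' @return named numeric vector over taxa, summing to one.
#' @export
closed_geometric_mean <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (any(x <= 0))
    stop("closed geometric mean requires strictly positive entries")
  g <- exp(colMeans(log(x)))
  g / sum(g)
}
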