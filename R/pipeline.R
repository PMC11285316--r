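#' Full cross-platform concordance analysis
#'
#' The package's central driver: runs the complete comparison between the
#' two platforms of a paired study — taxonomic overlap (global and per
#' sample), abundance correlation of compositional centres, alpha diversity
#' (rarefied Shannon, Chao1, Wilcoxon and Spearman), sparsity, and
#' beta-diversity structure (Aitchison PCoA, ANOSIM, PERMANOVA with
#' pairwise BH post-hoc, Procrustes, RV co-inertia), at each requested
#' rank, plus the RV-matrix PCA over all platform-by-rank ordinations and,
#' optionally, the machine-learning concordance (one-vs-one linear SVM and
#' random forest per platform, prediction/SV agreement and signature
#' similarity).
#'
#' The input tables are expected harmonized (synonym-mapped, ambiguous 16S
#' taxa merged); unnamed taxa are excluded internally for the
#' cross-platform statistics. Shotgun counts are genome-length normalized
#' before filtering when lengths are attached.
#'
#' @param paired a [paired_study()] at species rank.
#' @param ranks taxonomic ranks to analyse (default species, genus,
#'   family).
#' @param filter a [filter_spec()].
#' @param ml_ranks ranks at which to train classifiers (default same as
#'   `ranks`; `character(0)` skips the ML stage).
#' @param test_per_class stratified test-set size per class (default 10).
#' @param top_k_by_rank signature sizes per rank (default 50 species, 20
#'   genera, 10 families).
#' @param n_perm permutations for ANOSIM/PERMANOVA/Procrustes/RV (default
#'   999).
#' @param n_boot bootstrap replicates for CIs (default 2000).
#' @param seed master seed; stage seeds are derived from it.
#' @return object of class `platform_concordance`.
#' @export
concordance <- function(paired, ranks = c("species", "genus", "family"),
                        filter = filter_spec(),
                        ml_ranks = ranks, test_per_class = 10,
                        top_k_by_rank = c(species = 50, genus = 20,
                                          family = 10),
                        n_perm = 999, n_boot = 2000, seed = 1) {
  stopifnot(inherits(paired, "paired_study"))
  sg0 <- paired$shotgun
  if (!is.null(sg0$genome_lengths)) sg0 <- genome_length_normalize(sg0)
  named <- paired_study(exclude_unnamed(sg0), exclude_unnamed(paired$x16s),
                        paired$metadata)
  diagnosis <- paired$metadata$diagnosis
  out <- list(ranks = ranks, seed = seed, per_rank = list(),
              metadata = paired$metadata)
  configs <- list()
  for (rk in ranks) {
    tabs <- study_at_rank(named, rk)
    res <- list(
      overlap = global_overlap(named, rk),
      per_sample = per_sample_overlap(named, rk),
      abundance = abundance_correlation(named, rk))
    ## alpha diversity on raw (unfiltered, unnormalized) named tables
    raw <- study_at_rank(paired_study(exclude_unnamed(paired$shotgun),
                                      exclude_unnamed(paired$x16s),
                                      paired$metadata), rk)
    a_sg <- alpha_diversity(raw$shotgun, seed = seed + 11)
    a_16 <- alpha_diversity(raw$x16s, seed = seed + 12)
    res$alpha <- list(
      shotgun = a_sg, x16s = a_16,
      shannon = compare_alpha(a_sg, a_16, "shannon", diagnosis),
      chao1 = compare_alpha(a_sg, a_16, "chao1", diagnosis))
    res$sparsity <- sparsity_profile(named, rk)
    ## compositional pipeline per platform
    beta <- list()
    for (pl in c("shotgun", "x16s")) {
      tab <- prevalence_filter(tabs[[pl]], filter)
      clr <- clr_transform(replace_zeros(tab))
      d <- aitchison_distance(clr)
      ord <- pcoa(d)
      beta[[pl]] <- list(
        n_taxa = n_taxa(tab), clr = clr, pcoa = ord,
        anosim = anosim_test(d, diagnosis, n_perm, seed + 21),
        permanova = permanova(d, diagnosis, n_perm, seed + 22),
        pairwise = pairwise_permanova(d, diagnosis, n_perm, seed + 23))
    }
    res$beta <- beta
    res$procrustes <- procrustes_r(beta$shotgun$pcoa, beta$x16s$pcoa,
                                   n_perm, seed + 31)
    res$rv <- rv_coefficient(beta$shotgun$pcoa$coordinates,
                             beta$x16s$pcoa$coordinates, n_perm, seed + 32)
    configs[[paste0("shotgun_", rk)]] <- beta$shotgun$pcoa
    configs[[paste0("16S_", rk)]] <- beta$x16s$pcoa
    out$per_rank[[rk]] <- res
  }
  out$rv_matrix <- rv_matrix(configs)
  out$rv_pca <- rv_matrix_pca(out$rv_matrix)
  ## machine-learning concordance: one split shared by platforms and ranks
  if (length(ml_ranks)) {
    split <- stratified_split(diagnosis, test_per_class, seed = seed + 41)
    out$split <- split
    out$ml <- list()
    for (rk in ml_ranks) {
      k <- if (rk %in% names(top_k_by_rank)) top_k_by_rank[[rk]] else 50
      out$ml[[rk]] <- ml_concordance_at_rank(
        out$per_rank[[rk]]$beta, diagnosis, split, top_k = k,
        n_boot = n_boot, seed = seed + 42)
    }
  }
  class(out) <- "platform_concordance"
  out
}

# Train SVM + RF on both platforms at one rank and compare them.
ml_concordance_at_rank <- function(beta, diagnosis, split, top_k = 50,
                                   cost_grid = c(0.1, 1, 10, 100),
                                   n_trees_grid = c(500, 1000, 2000),
                                   min_node_grid = c(2, 3),
                                   n_boot = 2000, seed = 1) {
  y_tr <- diagnosis[split$train]
  y_te <- diagnosis[split$test]
  models <- list()
  for (pl in c("shotgun", "x16s")) {
    clr <- beta[[pl]]$clr
    for (alg in c("SVM", "RF")) {
      m <- tune_and_train(clr[split$train, , drop = FALSE], y_tr, alg,
                          cost_grid = cost_grid,
                          n_trees_grid = n_trees_grid,
                          min_node_grid = min_node_grid, seed = seed)
      m$test_predictions <- predict(m, clr[split$test, , drop = FALSE])
      m$train_accuracy <- accuracy(m$fitted_labels, y_tr)
      m$test_accuracy <- accuracy(m$test_predictions, y_te)
      m$test_ci <- accuracy_boot_ci(m$test_predictions, y_te,
                                    n_boot = n_boot, seed = seed)
      models[[paste(pl, alg, sep = "_")]] <- m
    }
  }
  comp <- list()
  for (alg in c("SVM", "RF")) {
    a <- models[[paste0("shotgun_", alg)]]
    b <- models[[paste0("x16s_", alg)]]
    comp[[alg]] <- list(
      train = agreement(a$fitted_labels, b$fitted_labels),
      test = agreement(a$test_predictions, b$test_predictions),
      signature = signature_compare(a, b, top_k = top_k, n_boot = n_boot,
                                    seed = seed),
      sv = if (alg == "SVM") sv_agreement(a, b))
  }
  list(models = models, comparison = comp, top_k = top_k)
}

#' @export
print.platform_concordance <- function(x, ...) {
  cat("platform_concordance over ranks:",
      paste(x$ranks, collapse = ", "), "\n")
  for (rk in x$ranks) {
    r <- x$per_rank[[rk]]
    cat(sprintf(
      " %-7s shared %d (%.1f%%/%.1f%%) | centre rho %.2f | procrustes r %.2f | RV %.2f\n",
      rk, r$overlap$n_shared, r$overlap$shared_over_16s,
      r$overlap$shared_over_shotgun, r$abundance$rho, r$procrustes$r,
      r$rv$rv))
  }
  if (!is.null(x$ml))
    cat(" ML ranks:", paste(names(x$ml), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.platform_concordance <- function(object, ...) {
  rows <- lapply(object$ranks, function(rk) {
    r <- object$per_rank[[rk]]
    data.frame(
      rank = rk, n_16s = r$overlap$n_16s, n_shotgun = r$overlap$n_shotgun,
      n_shared = r$overlap$n_shared,
      centre_rho = r$abundance$rho,
      shannon_rho = r$alpha$shannon$spearman,
      anosim_R_shotgun = r$beta$shotgun$anosim$R,
      anosim_R_16s = r$beta$x16s$anosim$R,
      procrustes_r = r$procrustes$r, rv = r$rv$rv,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.platform_concordance", "data.frame")
  out
}

#' @export
print.summary.platform_concordance <- function(x, ...) {
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Ordination scatter of both platforms
#'
#' Draws the first two principal coordinates of the shotgun and 16S
#' Aitchison PCoAs at one rank, colored by diagnosis.
#'
#' @param x a `platform_concordance`.
#' @param rank rank to plot (default the first analysed).
#' @param ... passed to [graphics::plot()].
#' @export
plot.platform_concordance <- function(x, rank = x$ranks[1], ...) {
  r <- x$per_rank[[rank]]
  cols <- c(control = "#2166ac", HRL = "#fdb863", CRC = "#b2182b")
  diag <- x$metadata$diagnosis
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (pl in c("shotgun", "x16s")) {
    ord <- r$beta[[pl]]$pcoa
    graphics::plot(ord$coordinates[, 1:2], col = cols[as.character(diag)],
                   pch = 19, xlab = sprintf("PCo1 (%.1f%%)", ord$explained[1]),
                   ylab = sprintf("PCo2 (%.1f%%)", ord$explained[2]),
                   main = paste(if (pl == "x16s") "16S" else pl, rank), ...)
  }
  invisible(x)
}

#' Run the full pipeline on study files and write reports
#'
#' Reads a study directory (as written by [write_study()]), runs
#' [concordance()], writes tidy tab-separated reports plus a JSON run
#' manifest recording the configuration, seeds and output paths.
#'
#' @param input_dir directory of study input files.
#' @param output_dir directory for reports (created if needed).
#' @param ranks,ml_ranks,n_perm,seed passed to [concordance()].
#' @param transposed input count tables are taxa x samples.
#' @return the run manifest (class `run_manifest`), invisibly; the
#'   `platform_concordance` object is attached as attribute `"result"`.
#' @export
run_all <- function(input_dir, output_dir,
                    ranks = c("species", "genus", "family"),
                    ml_ranks = ranks, n_perm = 999, seed = 1,
                    transposed = FALSE) {
  study <- read_study(input_dir, transposed = transposed)
  study$x16s <- merge_ambiguous(study$x16s)
  res <- concordance(study, ranks = ranks, ml_ranks = ml_ranks,
                     n_perm = n_perm, seed = seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  wt(summary(res), "concordance_summary.tsv")
  for (rk in ranks) {
    wt(res$per_rank[[rk]]$per_sample, paste0("per_sample_", rk, ".tsv"))
    wt(res$per_rank[[rk]]$beta$shotgun$pairwise,
       paste0("pairwise_permanova_shotgun_", rk, ".tsv"))
    wt(res$per_rank[[rk]]$beta$x16s$pairwise,
       paste0("pairwise_permanova_16s_", rk, ".tsv"))
  }
  rvk <- data.frame(dataset = rownames(res$rv_matrix), res$rv_matrix,
                    check.names = FALSE)
  wt(rvk, "rv_matrix.tsv")
  if (!is.null(res$ml)) {
    ml_rows <- list()
    for (rk in names(res$ml)) for (alg in c("SVM", "RF")) {
      cmp <- res$ml[[rk]]$comparison[[alg]]
      msg <- res$ml[[rk]]$models[[paste0("shotgun_", alg)]]
      m16 <- res$ml[[rk]]$models[[paste0("x16s_", alg)]]
      ml_rows[[paste(rk, alg)]] <- data.frame(
        rank = rk, algorithm = alg,
        train_acc_shotgun = msg$train_accuracy,
        train_acc_16s = m16$train_accuracy,
        test_acc_shotgun = msg$test_accuracy,
        test_acc_16s = m16$test_accuracy,
        agreement_train = cmp$train$agreement,
        agreement_test = cmp$test$agreement,
        kappa_train = cmp$train$kappa, kappa_test = cmp$test$kappa,
        kendall_tau = cmp$signature$tau,
        top_k_agreement = cmp$signature$top_k_agreement,
        stringsAsFactors = FALSE)
    }
    wt(do.call(rbind, ml_rows), "ml_concordance.tsv")
  }
  manifest <- structure(list(
    input_dir = normalizePath(input_dir),
    output_dir = normalizePath(output_dir),
    ranks = ranks, ml_ranks = ml_ranks, n_perm = n_perm,
    seeds = list(master = seed, alpha = seed + 11:12,
                 beta = seed + 21:23, procrustes = seed + 31,
                 rv = seed + 32, split = seed + 41, ml = seed + 42),
    outputs = paths,
    version = as.character(utils::packageVersion("metaconcord"))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "result") <- res
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$outputs), "reports in", x$output_dir, "\n")
  invisible(x)
}
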