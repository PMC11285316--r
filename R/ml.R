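DIAG_LEVELS <- c("control", "HRL", "CRC")

#' Stratified train/test split
#'
#' Draws exactly `test_per_class` samples per diagnosis class into the test
#' set (stratified random sampling); the remainder forms the training set.
#' Deterministic under a fixed seed; the same split is reused for both
#' platforms and all ranks so that cross-platform model comparisons are over
#' identical sample sets.
#'
#' @param labels factor (or character) of class labels, optionally named by
#'   sample id.
#' @param test_per_class test-set size per class (default 10).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_per_class = 10, seed = 1) {
  labels <- as.factor(labels)
  cnt <- table(labels)
  if (any(cnt < test_per_class))
    stop("class(es) smaller than test_per_class: ",
         paste(names(cnt)[cnt < test_per_class], collapse = ", "))
  set.seed(seed)
  test <- integer(0)
  for (lev in levels(labels)) {
    ix <- which(labels == lev)
    test <- c(test, sort(sample(ix, test_per_class)))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# Stratified k-fold assignment (vector of fold ids per sample).
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (lev in levels(as.factor(labels))) {
    ix <- sample(which(labels == lev))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# One-vs-one linear SVM ensemble over the three diagnosis pairs.
svm_ovo_fit <- function(x, y, cost) {
  levs <- levels(y)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    keep <- y %in% pr
    e1071::svm(x[keep, , drop = FALSE], factor(y[keep], levels = pr),
               kernel = "linear", cost = cost, scale = FALSE)
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  sv <- matrix(FALSE, nrow(x), length(models),
               dimnames = list(rownames(x), names(models)))
  for (k in seq_along(models)) {
    keep <- which(y %in% pairs[[k]])
    sv[keep[models[[k]]$index], k] <- TRUE
  }
  list(models = models, pairs = pairs, support_vectors = sv, cost = cost)
}

# Majority vote over the binary models; cyclic ties broken by the largest
# summed absolute decision value, then by class order control < HRL < CRC.
svm_ovo_predict <- function(fit, newx) {
  levs <- DIAG_LEVELS
  n <- nrow(newx)
  votes <- matrix(0, n, length(levs), dimnames = list(NULL, levs))
  mag <- matrix(0, n, length(levs), dimnames = list(NULL, levs))
  dec <- matrix(NA_real_, n, length(fit$models),
                dimnames = list(rownames(newx), names(fit$models)))
  for (k in seq_along(fit$models)) {
    pr <- fit$pairs[[k]]
    p <- stats::predict(fit$models[[k]], newx, decision.values = TRUE)
    dv <- drop(attr(p, "decision.values"))
    dec[, k] <- dv
    win <- as.character(p)
    for (i in seq_len(n)) {
      votes[i, win[i]] <- votes[i, win[i]] + 1
      mag[i, win[i]] <- mag[i, win[i]] + abs(dv[i])
    }
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      m <- mag[i, top]
      top <- top[m == max(m)]
    }
    pred[i] <- levs[top[1]]
  }
  list(class = factor(pred, levels = levs), decision_values = dec)
}

# Per-taxon mean absolute hyperplane weight across the binary SVMs.
svm_importance <- function(fit) {
  W <- vapply(fit$models, function(m) {
    w <- crossprod(m$coefs, m$SV)
    drop(w)
  }, numeric(ncol(fit$models[[1]]$SV)))
  rownames(W) <- colnames(fit$models[[1]]$SV)
  imp <- rowMeans(abs(W))
  attr(imp, "per_binary") <- abs(W)
  imp
}

#' Tune and train a diagnosis classifier
#'
#' Grid search by 5-fold stratified cross-validated accuracy on the training
#' samples, ties resolved toward the simpler model (smallest cost; fewest
#' trees, then smallest node size), followed by a refit on the full training
#' set. The SVM is a one-vs-one ensemble of three binary linear-kernel
#' models (control-HRL, control-CRC, HRL-CRC) combined by majority vote;
#' the random forest is multiclass directly. Fitted training labels are the
#' training-set predictions for SVM and the out-of-bag predictions for RF.
#'
#' @param x samples x taxa matrix of clr-transformed training abundances.
#' @param y factor of training labels (control/HRL/CRC).
#' @param algorithm `"SVM"` or `"RF"`.
#' @param cost_grid SVM cost candidates (default `c(0.1, 1, 10, 100)`).
#' @param n_trees_grid RF tree-count candidates (default
#'   `c(500, 1000, 2000)`).
#' @param min_node_grid RF minimum node size candidates (default `c(2, 3)`).
#' @param cv_folds number of cross-validation folds (default 5).
#' @param importance_type RF importance: `"impurity"` (mean decrease in node
#'   impurity, default) or `"permutation"`.
#' @param seed integer seed (cross-validation folds and forests).
#' @return object of class `model_result` with the fitted labels, the final
#'   model, per-taxon importances, support-vector membership (SVM), chosen
#'   hyperparameters and the CV accuracy table.
#' @export
tune_and_train <- function(x, y, algorithm = c("SVM", "RF"),
                           cost_grid = c(0.1, 1, 10, 100),
                           n_trees_grid = c(500, 1000, 2000),
                           min_node_grid = c(2, 3),
                           cv_folds = 5,
                           importance_type = c("impurity", "permutation"),
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  importance_type <- match.arg(importance_type)
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = DIAG_LEVELS)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  fold <- stratified_folds(y, cv_folds, seed = seed)

  grid <- if (algorithm == "SVM") {
    data.frame(cost = sort(cost_grid))
  } else {
    expand.grid(min_node = sort(min_node_grid),
                n_trees = sort(n_trees_grid))[, c("n_trees", "min_node")]
  }
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    accs <- rep(NA_real_, cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (!any(!tr)) next  # no validation samples in this fold
      if (nlevels(droplevels(y[tr])) < nlevels(y)) {
        fold <- stratified_folds(y, cv_folds, seed = seed + 1000L)
        tr <- fold != f
        if (!any(!tr)) next
      }
      if (algorithm == "SVM") {
        fit <- svm_ovo_fit(x[tr, , drop = FALSE], y[tr], grid$cost[g])
        pred <- svm_ovo_predict(fit, x[!tr, , drop = FALSE])$class
      } else {
        set.seed(seed + f)
        fit <- randomForest::randomForest(
          x[tr, , drop = FALSE], y[tr], ntree = grid$n_trees[g],
          nodesize = grid$min_node[g])
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      }
      accs[f] <- mean(pred == y[!tr])
    }
    cv_acc[g] <- mean(accs, na.rm = TRUE)
  }
  best <- which.max(cv_acc)  # first max = simplest by grid ordering

  if (algorithm == "SVM") {
    fit <- svm_ovo_fit(x, y, grid$cost[best])
    fitted <- svm_ovo_predict(fit, x)
    imp <- svm_importance(fit)
    res <- list(algorithm = "SVM",
                fitted_labels = fitted$class,
                decision_values = fitted$decision_values,
                support_vectors = fit$support_vectors,
                importance = imp,
                importance_per_binary = attr(imp, "per_binary"),
                hyperparameters = list(cost = grid$cost[best]),
                model = fit)
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x, y, ntree = grid$n_trees[best], nodesize = grid$min_node[best],
      importance = importance_type == "permutation")
    imp <- if (importance_type == "permutation")
      randomForest::importance(fit, type = 1)[, 1]
    else randomForest::importance(fit, type = 2)[, 1]
    res <- list(algorithm = "RF",
                fitted_labels = stats::predict(fit),  # out-of-bag
                decision_values = NULL,
                support_vectors = NULL,
                importance = imp,
                hyperparameters = list(n_trees = grid$n_trees[best],
                                       min_node = grid$min_node[best]),
                model = fit)
  }
  res$cv_accuracy <- data.frame(grid, cv_accuracy = cv_acc)
  res$train_ids <- rownames(x)
  res$seed <- seed
  class(res) <- "model_result"
  res
}

#' @export
print.model_result <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("model_result [%s]: %d training samples; %s; CV accuracy %.1f%%\n",
              x$algorithm, length(x$fitted_labels), hp,
              100 * max(x$cv_accuracy$cv_accuracy)))
  invisible(x)
}

#' Predict diagnosis labels from a trained model
#'
#' @param object a `model_result`.
#' @param newdata samples x taxa clr matrix with the model's feature
#'   columns.
#' @param ... unused.
#' @return factor of predicted labels (control/HRL/CRC).
#' @export
predict.model_result <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$algorithm == "SVM")
    svm_ovo_predict(object$model, newdata)$class
  else
    stats::predict(object$model, newdata)
}

#' Classification accuracy (percent)
#'
#' `100 * correct predictions / total predictions`.
#'
#' @param predictions,truth equal-length label vectors.
#' @return percentage in \[0, 100\].
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0) stop("empty prediction set")
  if (length(predictions) != length(truth)) stop("length mismatch")
  100 * mean(as.character(predictions) == as.character(truth))
}

#' Percentile bootstrap confidence interval for accuracy
#'
#' Resamples test indices with replacement `n_boot` times and reports the
#' percentile interval of the accuracy.
#'
#' @inheritParams accuracy
#' @param n_boot bootstrap replicates (default 2000).
#' @param conf_level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric vector `c(lower, upper)` in percent.
#' @export
accuracy_boot_ci <- function(predictions, truth, n_boot = 2000,
                             conf_level = 0.95, seed = 1) {
  ok <- as.character(predictions) == as.character(truth)
  if (!length(ok)) stop("empty prediction set")
  set.seed(seed)
  boots <- replicate(n_boot, 100 * mean(sample(ok, replace = TRUE)))
  a <- (1 - conf_level) / 2
  unname(stats::quantile(boots, c(a, 1 - a)))
}

#' Cross-platform prediction agreement
#'
#' Proportion of samples where the two platforms' models predict the same
#' label, with Cohen's kappa (three-category) and its asymptotic confidence
#' interval.
#'
#' @param pred_a,pred_b equal-length label vectors over the same samples in
#'   the same order.
#' @return list with `agreement` (proportion), `kappa`, `kappa_lower`,
#'   `kappa_upper`.
#' @export
agreement <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) stop("length mismatch")
  kc <- cohens_kappa_ci(pred_a, pred_b)
  list(agreement = mean(as.character(pred_a) == as.character(pred_b)),
       kappa = kc$kappa, kappa_lower = kc$lower, kappa_upper = kc$upper)
}

#' Support-vector matching between two SVM models
#'
#' Compares the per-sample support-vector membership of the two platforms'
#' one-vs-one SVMs, per binary sub-model, by agreement proportion and
#' Cohen's kappa (reported missing when a membership vector is constant).
#'
#' @param model_a,model_b SVM `model_result`s trained on the same training
#'   samples.
#' @return data.frame with one row per binary model: `pair`, `agreement`,
#'   `kappa`.
#' @export
sv_agreement <- function(model_a, model_b) {
  if (model_a$algorithm != "SVM" || model_b$algorithm != "SVM")
    stop("support-vector matching requires SVM models")
  if (!identical(model_a$train_ids, model_b$train_ids))
    stop("models were not trained on the same samples")
  pairs <- colnames(model_a$support_vectors)
  data.frame(
    pair = pairs,
    agreement = vapply(pairs, function(p)
      mean(model_a$support_vectors[, p] == model_b$support_vectors[, p]),
      numeric(1)),
    kappa = vapply(pairs, function(p)
      cohens_kappa(model_a$support_vectors[, p],
                   model_b$support_vectors[, p]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Taxa ranked by model importance
#'
#' RF: mean decrease in node impurity (or permutation importance if the
#' model was trained with it); SVM: mean absolute hyperplane weight across
#' the three binary models. Descending order, ties broken by name.
#'
#' @param model a `model_result`.
#' @return character vector of taxon labels, most important first.
#' @export
importance_ranking <- function(model) {
  imp <- model$importance
  names(imp)[order(-imp, names(imp))]
}

#' Microbial-signature similarity between two models
#'
#' Restricts both importance rankings to the taxa present in both models,
#' computes Kendall's tau-b over the importance ranks with a bootstrap
#' confidence interval (resampling taxa), and the top-k agreement
#' `100 * |top_k(a) intersect top_k(b)| / k` (conventional k: 50 species,
#' 20 genera, 10 families).
#'
#' @param model_a,model_b `model_result`s (or named importance vectors).
#' @param top_k signature size (default 50).
#' @param n_boot bootstrap replicates for the tau CI (default 2000).
#' @param seed integer seed.
#' @return object of class `signature_comparison`: list with `tau`,
#'   `tau_lower`, `tau_upper`, `p_value`, `top_k_agreement` (percent),
#'   `shared_top_taxa`, `n_shared`.
#' @export
signature_compare <- function(model_a, model_b, top_k = 50, n_boot = 2000,
                              seed = 1) {
  imp_a <- if (inherits(model_a, "model_result")) model_a$importance else model_a
  imp_b <- if (inherits(model_b, "model_result")) model_b$importance else model_b
  shared <- intersect(names(imp_a), names(imp_b))
  if (length(shared) < 3) stop("fewer than 3 shared taxa")
  a <- imp_a[shared]
  b <- imp_b[shared]
  tau <- stats::cor(a, b, method = "kendall")
  pv <- suppressWarnings(
    stats::cor.test(a, b, method = "kendall", exact = FALSE)$p.value)
  set.seed(seed)
  boots <- replicate(n_boot, {
    ix <- sample(length(shared), replace = TRUE)
    suppressWarnings(stats::cor(a[ix], b[ix], method = "kendall"))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  top_a <- names(a)[order(-a, names(a))][seq_len(min(top_k, length(a)))]
  top_b <- names(b)[order(-b, names(b))][seq_len(min(top_k, length(b)))]
  shared_top <- intersect(top_a, top_b)
  structure(list(
    tau = tau, tau_lower = unname(ci[1]), tau_upper = unname(ci[2]),
    p_value = pv,
    top_k = top_k,
    top_k_agreement = 100 * length(shared_top) / min(top_k, length(a)),
    shared_top_taxa = shared_top, n_shared = length(shared)),
    class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf(
    "signature_comparison: tau %.2f (95%% CI %.2f, %.2f); top-%d agreement %.0f%% over %d shared taxa\n",
    x$tau, x$tau_lower, x$tau_upper, x$top_k, x$top_k_agreement, x$n_shared))
  invisible(x)
}
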