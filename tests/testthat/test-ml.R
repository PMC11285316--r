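test_that("stratified split reproduces the screening-study design", {
  labels <- factor(rep(c("control", "HRL", "CRC"), c(51, 54, 51)),
                   levels = c("control", "HRL", "CRC"))
  sp <- stratified_split(labels, test_per_class = 10, seed = 5)
  expect_equal(length(sp$train), 126)
  expect_equal(length(sp$test), 30)
  expect_equal(as.vector(table(labels[sp$train])), c(41, 44, 41))
  expect_equal(as.vector(table(labels[sp$test])), c(10, 10, 10))
  expect_equal(sp, stratified_split(labels, test_per_class = 10, seed = 5))
  expect_false(identical(sp$test,
                         stratified_split(labels, 10, seed = 6)$test))

  bal <- factor(rep(c("control", "HRL", "CRC"), each = 30))
  expect_equal(length(stratified_split(bal, 10, seed = 1)$train), 60)
  expect_error(stratified_split(factor(rep(c("control", "HRL", "CRC"),
                                           c(5, 30, 30))), 10),
               "smaller")
})

# deterministic 3-class toy problem, linearly separable in 2 features
separable_xy <- function(n_per = 15, seed = 1, noise = 0.1) {
  set.seed(seed)
  y <- factor(rep(c("control", "HRL", "CRC"), each = n_per),
              levels = c("control", "HRL", "CRC"))
  centers <- rbind(control = c(0, 0), HRL = c(4, 0), CRC = c(0, 4))
  x <- centers[as.character(y), ] + matrix(rnorm(2 * length(y), 0, noise),
                                           ncol = 2)
  x <- cbind(x, matrix(rnorm(length(y) * 3), ncol = 3))  # noise features
  colnames(x) <- paste0("t", 1:5)
  rownames(x) <- paste0("S", seq_along(y))
  list(x = x, y = y)
}

test_that("SVM one-vs-one and RF learn separable classes perfectly", {
  d <- separable_xy()
  for (alg in c("SVM", "RF")) {
    m <- tune_and_train(d$x, d$y, alg, cost_grid = 1, n_trees_grid = 200,
                        min_node_grid = 2, seed = 2)
    if (alg == "SVM")
      expect_equal(accuracy(m$fitted_labels, d$y), 100)
    pred <- predict(m, d$x)
    expect_equal(accuracy(pred, d$y), 100)
    expect_equal(length(m$importance), 5)
    # the two informative features dominate the importance ranking
    expect_setequal(importance_ranking(m)[1:2], c("t1", "t2"))
  }
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(31)
  d <- separable_xy(n_per = 20)
  accs <- replicate(6, {
    y_sh <- sample(d$y)
    m <- tune_and_train(d$x, y_sh, "SVM", cost_grid = 1, seed = sample.int(1e4, 1))
    mean(m$cv_accuracy$cv_accuracy)
  })
  expect_equal(mean(accs) * 100, 33.3, tolerance = 8)
})

test_that("accuracy and its bootstrap CI behave at the extremes", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(accuracy(rep(c("a", "b"), each = 15),
                        rep(c("a", "c"), each = 15)), 50)
  expect_error(accuracy(character(0), character(0)), "empty")
  ci <- accuracy_boot_ci(c("a", "a"), c("a", "a"), n_boot = 100)
  expect_equal(ci, c(100, 100))
  # random 3-class guessing on 30 samples: CI width around 34 points
  set.seed(32)
  pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
  ci2 <- accuracy_boot_ci(pred, truth, n_boot = 2000, seed = 1)
  expect_equal(ci2[2] - ci2[1], 34, tolerance = 12)
})

test_that("prediction agreement and kappa match expectations", {
  a <- factor(c("control", "HRL", "CRC", "CRC"))
  expect_equal(agreement(a, a)$agreement, 1)
  expect_equal(agreement(a, a)$kappa, 1)
  b <- factor(c("HRL", "CRC", "control", "HRL"))
  expect_equal(agreement(a, b)$agreement, 0)
  set.seed(33)
  u <- sample(c("control", "HRL", "CRC"), 1e4, replace = TRUE)
  v <- sample(c("control", "HRL", "CRC"), 1e4, replace = TRUE)
  ag <- agreement(u, v)
  expect_equal(ag$agreement, 1 / 3, tolerance = 0.03)
  expect_equal(ag$kappa, 0, tolerance = 0.03)
  expect_true(ag$kappa_lower <= ag$kappa && ag$kappa <= ag$kappa_upper)
})

test_that("support-vector matching compares per-binary memberships", {
  d <- separable_xy(n_per = 12, noise = 0.6)
  m1 <- tune_and_train(d$x, d$y, "SVM", cost_grid = 1, seed = 3)
  m2 <- tune_and_train(d$x, d$y, "SVM", cost_grid = 1, seed = 4)
  sv <- sv_agreement(m1, m2)
  expect_equal(nrow(sv), 3)
  expect_equal(sv$agreement, rep(1, 3))  # same data, same model
  expect_equal(sv$kappa, rep(1, 3))
  m3 <- tune_and_train(d$x, d$y, "RF", n_trees_grid = 100, min_node_grid = 2,
                       seed = 3)
  expect_error(sv_agreement(m1, m3), "SVM")
})

test_that("signature comparison: tau, CI and top-k agreement", {
  imp_a <- stats::setNames(seq(100, 1), paste0("t", 1:100))
  same <- signature_compare(imp_a, imp_a, top_k = 20, n_boot = 100)
  expect_equal(same$tau, 1)
  expect_equal(same$top_k_agreement, 100)

  rev <- signature_compare(imp_a, stats::setNames(seq(1, 100),
                                                  paste0("t", 1:100)),
                           top_k = 100, n_boot = 100)
  expect_equal(rev$tau, -1)
  expect_equal(rev$top_k_agreement, 100)  # k = all taxa
  rev20 <- signature_compare(imp_a,
                             stats::setNames(seq(1, 100), paste0("t", 1:100)),
                             top_k = 20, n_boot = 100)
  expect_equal(rev20$top_k_agreement, 0)

  # tau-b equals the pair-enumeration oracle, with ties
  set.seed(34)
  for (r in 1:10) {
    a <- stats::setNames(sample(1:8, 12, replace = TRUE), paste0("t", 1:12))
    b <- stats::setNames(sample(1:8, 12, replace = TRUE), paste0("t", 1:12))
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(signature_compare(a, b, top_k = 5, n_boot = 10)$tau,
                 oracle_kendall_taub(a, b), tolerance = 1e-10)
  }

  # random rankings of 100 taxa at k = 50: hypergeometric mean 50%
  set.seed(35)
  agree <- replicate(300, {
    a <- stats::setNames(sample(100), paste0("t", 1:100))
    b <- stats::setNames(sample(100), paste0("t", 1:100))
    signature_compare(a, b, top_k = 50, n_boot = 2)$top_k_agreement
  })
  expect_equal(mean(agree), 50, tolerance = 2)
  expect_error(signature_compare(imp_a[1:2], imp_a[1:2]), "3 shared")
})

test_that("planted informative features rank first across seeds", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    y <- factor(rep(c("control", "HRL", "CRC"), each = 10),
                levels = c("control", "HRL", "CRC"))
    x <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(NULL, paste0("t", 1:20)))
    x[, 1] <- x[, 1] + c(control = 0, HRL = 2, CRC = 4)[as.character(y)]
    m <- tune_and_train(x, y, "RF", n_trees_grid = 300, min_node_grid = 2,
                        seed = seed)
    hits <- hits + (importance_ranking(m)[1] == "t1")
  }
  expect_gte(hits, 9)
})
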