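test_that("genome-length normalization removes length bias, keeps totals", {
  gl <- c("Genus_A sp01" = 2e6, "Genus_A sp02" = 4e6)
  tab <- make_table(rbind(c(100, 100), c(30, 10)),
                    genome_lengths = gl)
  out <- genome_length_normalize(tab)
  p <- out$counts[1, ] / sum(out$counts[1, ])
  expect_equal(unname(p), c(2 / 3, 1 / 3))
  expect_equal(rowSums(out$counts), rowSums(tab$counts))

  # equal lengths: proportions unchanged
  same <- make_table(rbind(c(100, 50)), genome_lengths = c(
    "Genus_A sp01" = 3e6, "Genus_A sp02" = 3e6))
  outs <- genome_length_normalize(same)
  expect_equal(outs$counts[1, ] / sum(outs$counts[1, ]),
               same$counts[1, ] / sum(same$counts[1, ]))

  # missing length rejected by name
  bad <- make_table(rbind(c(1, 1)), genome_lengths = c("Genus_A sp01" = 1e6))
  expect_error(genome_length_normalize(bad), "sp02")
  # not applicable to 16S
  expect_error(genome_length_normalize(make_table(rbind(c(1, 1)),
                                                  platform = "16S")),
               "shotgun")
})

test_that("prevalence filter applies the ceil(5% of samples) rule", {
  # one sample of 156 at 50% abundance: 1 < ceil(0.05*156) = 8 -> removed
  counts <- matrix(0, 156, 2, dimnames = list(sprintf("S%03d", 1:156), NULL))
  counts[, 1] <- 100
  counts[1, 2] <- 100
  tab <- make_table(counts)
  out <- prevalence_filter(tab, filter_spec())
  expect_equal(taxa_names(out), "Genus_A sp01")

  # 0.2% abundance in 10% of samples passes the default thresholds
  counts2 <- matrix(1000, 20, 2, dimnames = list(sprintf("S%02d", 1:20), NULL))
  counts2[, 2] <- 0
  counts2[1:2, 2] <- 2.1  # 2.1/1002.1 = 0.21%
  tab2 <- make_table(counts2)
  expect_equal(n_taxa(prevalence_filter(tab2, filter_spec())), 2)

  # zero thresholds: identity
  expect_equal(n_taxa(prevalence_filter(tab2, filter_spec(0, 0))), 2)
})

test_that("prevalence filter is monotone in both thresholds", {
  for (seed in 1:10) {
    tab <- random_table(12, 15, 100, seed = seed)
    strict <- taxa_names(prevalence_filter(tab, filter_spec(0.3, 0.05)))
    lax1 <- taxa_names(prevalence_filter(tab, filter_spec(0.1, 0.05)))
    lax2 <- taxa_names(prevalence_filter(tab, filter_spec(0.3, 0.01)))
    expect_true(all(strict %in% lax1))
    expect_true(all(strict %in% lax2))
  }
})

test_that("zero replacement imputes below detection and preserves ratios", {
  tab <- make_table(rbind(c(0, 1, 1), c(2, 3, 5)))
  out <- replace_zeros(tab)
  expect_true(all(out$counts > 0))
  expect_equal(rowSums(out$counts), c(1, 1), ignore_attr = TRUE)
  # imputed part sits strictly below the smallest observed proportion
  expect_lt(out$counts[1, 1], 0.5)
  expect_gt(out$counts[1, 1], 0)
  # originally non-zero parts keep their ratio exactly
  expect_equal(out$counts[1, 2] / out$counts[1, 3], 1)
  expect_equal(out$counts[2, ] / sum(out$counts[2, ]),
               tab$counts[2, ] / sum(tab$counts[2, ]))

  # randomized: all pairwise ratios among non-zero parts preserved to 1e-9
  for (seed in 1:10) {
    rt <- random_table(5, 8, 60, seed = seed)
    rz <- replace_zeros(rt)
    for (i in seq_len(nrow(rt$counts))) {
      nz <- which(rt$counts[i, ] > 0)
      if (length(nz) >= 2) {
        before <- rt$counts[i, nz[1]] / rt$counts[i, nz[2]]
        after <- rz$counts[i, nz[1]] / rz$counts[i, nz[2]]
        expect_equal(after, before, tolerance = 1e-9)
      }
    }
  }
  # a fully-zero sample is rejected
  allz <- make_table(rbind(c(0, 0), c(1, 2)))
  expect_error(replace_zeros(allz), "all-zero")
})

test_that("imputed zeros stay below the sample detection limit", {
  for (seed in 1:10) {
    rt <- random_table(6, 10, 500, seed = seed + 50)
    rz <- replace_zeros(rt)
    for (i in seq_len(nrow(rt$counts))) {
      zero <- rt$counts[i, ] == 0
      if (any(zero)) {
        min_obs <- min(rz$counts[i, !zero])
        expect_lt(max(rz$counts[i, zero]), min_obs)
      }
    }
  }
})

test_that("clr transform matches the closed form and is scale invariant", {
  tab <- make_table(rbind(c(1, 1, 1, 1)))
  expect_equal(unname(clr_transform(tab)[1, ]), rep(0, 4))

  x <- matrix(c(2, 2, 8), 1, dimnames = list("S1", c("a", "b", "c")))
  g <- 32^(1 / 3)
  expect_equal(unname(clr_transform(x)[1, ]),
               c(log(2 / g), log(2 / g), log(8 / g)))
  expect_equal(unname(clr_transform(x)[1, ]),
               c(-0.462, -0.462, 0.924), tolerance = 1e-3)

  # rows sum to zero; clr(c x) = clr(x); clr o closure = clr
  set.seed(4)
  y <- matrix(rexp(40) + 0.1, 5, 8, dimnames = list(paste0("S", 1:5),
                                                    paste0("t", 1:8)))
  expect_equal(rowSums(clr_transform(y)), rep(0, 5), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(clr_transform(y * 37), clr_transform(y))
  expect_equal(clr_transform(y / rowSums(y)), clr_transform(y))
  expect_error(clr_transform(cbind(y, 0)), "positive")
})

test_that("median binarization codes strictly-above-median as 1", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(0, 0, 5, 0))
  rownames(x) <- paste0("S", 1:4)
  b <- median_binarize(x)
  expect_equal(unname(b[, "a"]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(b[, "b"]), rep(0L, 4))       # ties are 0
  expect_equal(unname(b[, "c"]), c(0L, 0L, 1L, 0L))
})

test_that("closed geometric mean is the compositional centre", {
  # identical compositions: centre equals the composition
  tab <- make_table(rbind(c(2, 6), c(1, 3)))
  expect_equal(unname(closed_geometric_mean(tab)), c(0.25, 0.75))

  # two samples (0.5,0.5) and (0.8,0.2): centre ~ (sqrt(.4), sqrt(.1))
  tab2 <- make_table(rbind(c(0.5, 0.5), c(0.8, 0.2)))
  ctr <- closed_geometric_mean(tab2)
  expect_equal(unname(ctr), c(sqrt(0.4), sqrt(0.1)) /
                 (sqrt(0.4) + sqrt(0.1)))
  expect_equal(unname(ctr), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # closure on random tables
  set.seed(9)
  y <- matrix(rexp(60) + 0.01, 6, 10)
  expect_equal(sum(closed_geometric_mean(y)), 1, tolerance = 1e-12)
})
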