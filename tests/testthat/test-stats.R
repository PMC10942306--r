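test_that("signed-rank score equals the normalised Wilcoxon W+ statistic", {
  expect_equal(signed_rank_score(c(1, 2, 3, 4, 5)), 1)
  expect_equal(signed_rank_score(-(1:4)), 0)
  expect_equal(signed_rank_score(c(1, -2, 3)), (1 + 3) / 6)
  expect_true(is.na(signed_rank_score(c(0, 0))))
  # antisymmetry and agreement with wilcox.test's V for all samples n <= 8
  set.seed(1)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) == 0) next
    s <- signed_rank_score(d)
    expect_equal(s, 1 - signed_rank_score(-d))
    v <- suppressWarnings(wilcox.test(d)$statistic)
    expect_equal(s, unname(v) / (length(d) * (length(d) + 1) / 2))
  }
})

test_that("pseudobulk depth-normalises before averaging and sums to one", {
  m <- rbind(c(2, 0), c(1, 1))
  expect_equal(pseudobulk_profile(m), c(0.75, 0.25))
  one <- matrix(c(3, 1), 1)
  expect_equal(pseudobulk_profile(one), c(0.75, 0.25))
  set.seed(2)
  r <- matrix(rpois(200, 3), 20)
  expect_equal(sum(pseudobulk_profile(r)), 1)
  withzero <- rbind(c(0, 0), c(2, 2))
  expect_warning(pb <- pseudobulk_profile(withzero), "zero-depth")
  expect_equal(pb, c(0.5, 0.5))
})

test_that("LISI is bounded, permutation-invariant and separates mixing regimes", {
  set.seed(5)
  # single label level
  e <- matrix(rnorm(40), 20)
  expect_equal(lisi_score(e, rep("a", 20), perplexity = 5)$per_cell, rep(1, 20))
  # random labels in one Gaussian: near-complete mixing
  n <- 2000
  emb <- matrix(rnorm(n * 2), n)
  lab <- sample(c("a", "b"), n, TRUE)
  s <- lisi_score(emb, lab)
  expect_gt(s$mean, 1.8); expect_lte(s$mean, 2.0 + 1e-9)
  expect_true(all(s$per_cell >= 1 - 1e-9 & s$per_cell <= 2 + 1e-9))
  # permutation invariance of the mean over cells
  perm <- sample(n)
  s2 <- lisi_score(emb[perm, ], lab[perm])
  expect_equal(sort(s2$per_cell), sort(s$per_cell), tolerance = 1e-10)
  # well-separated clusters: no mixing
  emb2 <- rbind(matrix(rnorm(400, 0), 200), matrix(rnorm(400, 50), 200))
  lab2 <- rep(c("a", "b"), each = 200)
  expect_lt(lisi_score(emb2, lab2)$mean, 1.1)
  expect_error(lisi_score(emb[1:10, ], lab[1:10], perplexity = 30), "perplexity")
})

test_that("AUROC equals brute-force pair counting with half-ties", {
  expect_equal(auroc(c(0.9, 0.4, 0.6), c(1, 0, 1)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(1:4, rep(1, 4))))
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    s <- round(runif(n), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(p = which(y == 1), q = which(y == 0))
    brute <- mean(ifelse(s[pairs$p] > s[pairs$q], 1,
                         ifelse(s[pairs$p] == s[pairs$q], 0.5, 0)))
    expect_equal(auroc(s, y), brute)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- rnorm(60); y <- rbinom(60, 1, plogis(s))
  if (length(unique(y)) == 2) {
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(s, y), ref)
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(3:8, 1))
    n <- length(p)
    # independent step-up: q_(i) = min_{j >= i} p_(j) * n / j
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
    brute <- numeric(n); brute[o] <- pmin(q_sorted, 1)
    expect_equal(bh_fdr(p), brute)
    # monotone in p after sorting
    expect_true(all(diff(bh_fdr(p)[o]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("the default hyperparameter grid has 18 configurations", {
  g <- hyperparameter_grid()
  expect_equal(nrow(g), 18L)
  expect_equal(nrow(dplyr::distinct(g)), 18L)
  expect_setequal(unique(g$latent_dim), c(25, 50, 100))
  expect_setequal(unique(g$min_wavelength), c(1, 2 * pi))
  expect_setequal(unique(g$lambda_mse), c(1, 100, 10000))
})

test_that("rank-sum model selection picks dominating configs, ties by order", {
  g <- tibble::tibble(id = 1:3,
                      pearson = c(0.9, 0.5, 0.4),
                      lisi = c(1.9, 1.2, 1.1))
  expect_equal(select_model(g, c("pearson", "lisi"))$id, 1)
  # criterion ranks (1,2), (2,1), (3,3): third never selected, tie -> first
  g2 <- tibble::tibble(id = 1:3, a = c(3, 2, 1), b = c(2, 3, 1))
  expect_equal(select_model(g2, c("a", "b"))$id, 1)
  expect_equal(select_model(g2, c("a", "b"))$rank_sum, 3)
  # "loss" columns are minimised
  g3 <- tibble::tibble(id = 1:2, trans_loss = c(0.1, 5), pearson = c(0.5, 0.5))
  expect_equal(select_model(g3, c("trans_loss", "pearson"))$id, 1)
  expect_error(select_model(g3, "missing_metric"), "absent")
  g4 <- g3; g4$pearson[1] <- NA
  expect_error(select_model(g4, c("pearson")), "finite")
})

test_that("peakwise evaluation filters rare peaks and detects signal vs null", {
  set.seed(6)
  n <- 500
  truth <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
                 rare = c(rep(1, 20), rep(0, n - 20)))  # 4% accessible
  pred_good <- truth[, 1:2] * 0.9 + 0.05 + matrix(runif(2 * n, 0, 0.01), n)
  pred <- cbind(pred_good, rare = runif(n))
  r <- evaluate_peakwise(pred, truth)
  expect_equal(nrow(r), 2L)              # 'rare' excluded at the 5% threshold
  expect_false("rare" %in% r$peak)
  expect_equal(r$auroc, c(1, 1))
  expect_true(all(r$significant))
  expect_equal(attr(r, "frac_significant"), 1)
  # independent predictions: mean AUROC ~ 0.5
  pred_null <- matrix(runif(2 * n), n)
  r0 <- evaluate_peakwise(pred_null, truth[, 1:2])
  expect_lt(abs(mean(r0$auroc) - 0.5), 0.05)
  expect_error(evaluate_peakwise(matrix(runif(n)), cbind(truth[, "rare"])),
               "filter")
})

test_that("differential direction scores recover shifts and stay near 0.5 under the null", {
  set.seed(7)
  t1 <- matrix(rnorm(200 * 200), 200)
  up <- t1 + 1
  expect_equal(unname(differential_direction_score(t1, up)),
               rep(1, 200))
  null <- t1 + matrix(rnorm(200 * 200), 200)
  s0 <- differential_direction_score(t1, null)
  expect_gt(mean(s0 >= 0.4 & s0 <= 0.6), 0.95)
  # ensemble of one: the median is the score itself
  expect_equal(differential_direction_score(t1[, 1, drop = FALSE],
                                            up[, 1, drop = FALSE]),
               c(1))
})
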