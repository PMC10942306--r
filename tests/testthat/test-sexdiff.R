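test_that("consistent-bias gene calling follows the score and expression filters", {
  tab <- tibble::tibble(
    gene = rep(c("g1", "g2", "g3", "g4"), each = 3),
    cell_type = "ct",
    time_days = rep(c(8, 8.5, 9), 4),
    score = c(0.7, 0.8, 0.65,    # g1: always > 0.5
              0.7, 0.45, 0.8,    # g2: dips below
              0.2, 0.3, 0.1,     # g3: always < 0.5
              0.9, 0.9, 0.9),    # g4: high but lowly expressed at one tp
    n_cells = 60,
    mean_expr_F = c(rep(10, 3), rep(10, 3), rep(10, 3), c(10, 0.001, 10)),
    mean_expr_M = c(rep(10, 3), rep(10, 3), rep(10, 3), c(10, 0.001, 10)))
  class(tab) <- c("sexbias_table", class(tab))
  sets <- consistent_bias_genes(tab, "ct")
  expect_equal(sets$female_set, "g1")
  expect_equal(sets$male_set, "g3")     # g4 excluded by the top-half filter
  expect_false("g2" %in% unlist(sets))

  # below the cell-count threshold: nothing qualifies
  tab$n_cells <- 20
  expect_warning(empty <- consistent_bias_genes(tab, "ct"), "qualifying")
  expect_length(empty$female_set, 0)
})

test_that("gene-set shift test matches exact enumeration and complements on reversal", {
  sc <- c(a1 = 0.9, a2 = 0.8, b1 = 0.2, b2 = 0.1)
  expect_equal(geneset_shift_test(sc, c("a1", "a2"), c("b1", "b2")), 1 / 6)
  # identical distributions at large n: p near 0.5
  set.seed(8)
  sc2 <- setNames(runif(400), paste0("g", 1:400))
  p <- geneset_shift_test(sc2, paste0("g", 1:200), paste0("g", 201:400))
  expect_gt(p, 0.2); expect_lt(p, 0.8)
  # one-sided complement (no ties, n <= 8): p + p' = 1 + P(W = w_obs)
  set.seed(9)
  for (i in 1:10) {
    a <- round(runif(3), 3); b <- round(runif(4), 3)
    s <- setNames(c(a, b), paste0("g", 1:7))
    p1 <- geneset_shift_test(s, paste0("g", 1:3), paste0("g", 4:7))
    p2 <- geneset_shift_test(s, paste0("g", 4:7), paste0("g", 1:3))
    w <- sum(rank(c(a, b))[1:3]) - 6
    tie_mass <- dwilcox(w, 3, 4)
    expect_equal(p1 + p2, 1 + tie_mass, tolerance = 1e-10)
  }
  expect_error(geneset_shift_test(sc, "zz", "b1"), "intersect")
})

test_that("PPI odds ratio matches the hand-computed corrected table", {
  graph <- data.frame(from = "a1", to = "x1")
  r <- ppi_odds_ratio_test(graph, female_autosomal = c("a1", "a2"),
                           female_xlinked = "x1",
                           autosomal_universe = c("a1", "a2", "b1", "b2"),
                           n_perm = 10, seed = 1, min_edges = 1)
  expect_equal(r$odds_ratio, (1.5 / 1.5) / (0.5 / 2.5))
  # too few interactions: test skipped
  r2 <- ppi_odds_ratio_test(graph, c("a1", "a2"), "x1",
                            c("a1", "a2", "b1", "b2"), min_edges = 50)
  expect_true(is.na(r2$odds_ratio))
  expect_error(ppi_odds_ratio_test(graph, "a1", "x1", character(0)), "universe")
})

test_that("PPI permutation p-value is calibrated under the null", {
  set.seed(10)
  genes <- paste0("a", 1:40)
  xg <- paste0("x", 1:5)
  edges <- data.frame(from = sample(genes, 120, TRUE),
                      to = sample(xg, 120, TRUE))
  hits <- vapply(1:20, function(i) {
    cand <- sample(genes, 8)   # drawn from the null itself
    r <- ppi_odds_ratio_test(edges, cand, xg, genes, n_perm = 50,
                             seed = i, min_edges = 10)
    r$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  r <- hypergeometric_enrichment(paste0("g", 1:5),
                                 list(t1 = paste0("g", c(1:4))),
                                 paste0("g", 1:10))
  expect_equal(r$p, choose(4, 4) * choose(6, 1) / choose(10, 5))
  # zero overlap has p = 1 under the upper-tail convention
  r2 <- hypergeometric_enrichment(c("g1", "g2"), list(t = c("g9", "g10")),
                                  paste0("g", 1:10))
  expect_equal(r2$p, 1)
  # study = universe: every overlap maximal, p = 1
  r3 <- hypergeometric_enrichment(paste0("g", 1:10),
                                  list(t1 = "g1", t2 = paste0("g", 1:3)),
                                  paste0("g", 1:10))
  expect_equal(r3$p, c(1, 1))
  expect_error(hypergeometric_enrichment("g1", list(t = "g1"), character(0)),
               "universe")
})
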