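test_that("profile prediction is deterministic and depth-normalised", {
  sim <- micro_sim()
  m <- micro_rna_model()
  idx <- which(sim$data$cells$modality == "RNA")[1:10]
  p1 <- predict_profiles(m, sim$data, idx, target_time = 8.25)
  p2 <- predict_profiles(m, sim$data, idx, target_time = 8.25)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 10), tolerance = 1e-8)
  expect_error(predict_profiles(m, sim$data, idx, 8.25,
                                target_condition = "X"), "condition")
  # single-cell wrapper agrees with the matrix form
  pp <- predict_profile(m, sim$data, idx[1], target_time = 8.25)
  expect_equal(unname(pp$values), unname(p1[1, ]))
  expect_s3_class(tidy(pp), "tbl_df")
})

test_that("self-reconstruction beats a permuted-feature control", {
  sim <- micro_sim()
  m <- micro_rna_model()
  cells <- sim$data$cells
  idx <- which(cells$modality == "RNA")[1:40]
  x <- as.matrix(sim$data$counts[idx, m$feature_cols])
  xn <- x / pmax(rowSums(x), 1)
  per_cell <- vapply(seq_along(idx), function(i) {
    pred <- predict_profiles(m, sim$data, idx[i],
                             target_time = cells$time_days[idx[i]])
    cor(pred[1, ], xn[i, ])
  }, numeric(1))
  set.seed(1)
  perm <- vapply(seq_along(idx), function(i) {
    pred <- predict_profiles(m, sim$data, idx[i],
                             target_time = cells$time_days[idx[i]])
    cor(sample(pred[1, ]), xn[i, ])
  }, numeric(1))
  expect_gt(mean(per_cell), mean(perm))
  expect_gt(mean(per_cell), 0.2)
})

test_that("trajectories are grid-consistent and smooth", {
  sim <- micro_sim()
  m <- micro_rna_model()
  cell <- which(sim$data$cells$modality == "RNA")[1]
  tg <- seq(7.5, 9, by = 0.01)
  tr <- predict_trajectory(m, sim$data, cell, tg)
  expect_equal(dim(tr), c(151L, length(m$feature_ids)))
  # single-point grid equals a plain prediction
  tr1 <- predict_trajectory(m, sim$data, cell, 8.25)
  p1 <- predict_profiles(m, sim$data, cell, target_time = 8.25)
  expect_equal(unname(tr1[1, ]), unname(p1[1, ]))
  # row-to-row L2 change shrinks when the grid spacing halves
  step_change <- function(h) {
    g <- seq(8, 8.5, by = h)
    t <- predict_trajectory(m, sim$data, cell, g)
    max(sqrt(rowSums(diff(t)^2)))
  }
  d1 <- step_change(0.05); d2 <- step_change(0.025)
  expect_lt(d2, d1 * 1.05)
  expect_error(predict_trajectory(m, sim$data, cell, numeric(0)), "nonempty")
  expect_error(predict_trajectory(m, sim$data, cell, c(9, 8)), "increasing")
})

test_that("ensemble median is the element-wise median and is order-invariant", {
  sim <- micro_sim()
  splits <- make_splits(sim$data, split_spec(seed = 1))
  models <- lapply(1:3, function(s) {
    train_single_modality(sim$data, splits,
                          micro_config(seed = s, max_epochs = 2L))
  })
  idx <- which(sim$data$cells$modality == "RNA")[1:5]
  one <- ensemble_median(models[1], data = sim$data, cells = idx,
                         target_time = 8.25)
  expect_equal(one, predict_profiles(models[[1]], sim$data, idx,
                                     target_time = 8.25))
  em <- ensemble_median(models, data = sim$data, cells = idx,
                        target_time = 8.25)
  preds <- lapply(models, predict_profiles, data = sim$data, cells = idx,
                  target_time = 8.25)
  brute <- apply(array(unlist(preds), c(5, ncol(one), 3)), c(1, 2), median)
  expect_equal(unname(em), unname(brute))
  em_rev <- ensemble_median(rev(models), data = sim$data, cells = idx,
                            target_time = 8.25)
  expect_equal(em, em_rev)
})

test_that("neighbour aggregation sums ranks and applies the shortlist exclusion", {
  # 1 model: plain top-k by distance
  E <- matrix(c(0, 0,  1, 0,  2, 0,  3, 0,  4, 0, 10, 0), ncol = 2,
              byrow = TRUE,
              dimnames = list(c("q", "a", "b", "c", "d", "e"), NULL))
  expect_equal(aggregate_neighbors(list(E), "q", k_list = 25, k_keep = 4),
               c("a", "b", "c", "d"))
  # two models with opposite ranks: ties broken by id sort order
  E2 <- E[c("q", "b", "a", "c", "d", "e"), ]
  rownames(E2) <- c("q", "a", "b", "c", "d", "e")
  got <- aggregate_neighbors(list(E, E2), "q", k_list = 25, k_keep = 2)
  expect_equal(got, c("a", "b"))
  # a cell outside one model's shortlist is excluded entirely
  E3 <- E
  E3["b", ] <- c(1000, 0)   # b falls out of model 2's top-3
  got2 <- suppressWarnings(aggregate_neighbors(list(E, E3), "q",
                                               k_list = 3, k_keep = 4))
  expect_false("b" %in% got2)
  expect_warning(aggregate_neighbors(list(E, E3), "q", k_list = 2, k_keep = 4),
                 "survive")
})
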