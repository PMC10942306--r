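test_that("multimodal loss components decompose additively and match an oracle", {
  sim <- micro_sim()
  mm <- micro_mm_model()
  atac_idx <- which(sim$data$cells$modality == "ATAC")[1:20]
  pairs <- coassay_pairs(sim$data)[1:3, , drop = FALSE]
  L <- multimodal_losses(mm, sim$data, atac_idx, pairs)
  expect_equal(L$loss_multi,
               L$loss_atac + mm$lambda_mse * L$loss_align +
                 L$loss_trans_ab + L$loss_trans_ba)
  # lambda = 0 removes the alignment term only
  mm0 <- mm; mm0$lambda_mse <- 0
  L0 <- multimodal_losses(mm0, sim$data, atac_idx, pairs)
  expect_equal(L0$loss_multi, L0$loss_atac + L0$loss_trans_ab + L0$loss_trans_ba)
  expect_equal(L0$loss_atac, L$loss_atac)

  # brute-force recomputation of every term on the 3-pair toy batch
  d <- sim$data
  fwd <- function(p, xin, te, cond, bat) {
    h <- cbind(xin, te, cond, bat)
    for (l in p$enc$trunk) h <- pmax(sweep(h %*% l$W, 2, l$b, "+"), 0)
    sweep(h %*% p$enc$mean$W, 2, p$enc$mean$b, "+")
  }
  cvr <- chronocell:::model_covariates(mm$rna, d$cells$time_days[pairs[, 1]],
                                       d$cells$condition[pairs[, 1]],
                                       d$cells$batch[pairs[, 1]])
  cva <- chronocell:::model_covariates(mm$atac, d$cells$time_days[pairs[, 2]],
                                       d$cells$condition[pairs[, 2]],
                                       d$cells$batch[pairs[, 2]])
  xr <- as.matrix(d$counts[pairs[, 1], mm$rna$feature_cols])
  xa <- as.matrix(d$counts[pairs[, 2], mm$atac$feature_cols])
  m_r <- fwd(mm$rna$params, log1p(xr), cvr$te, cvr$cond, cvr$batch)
  m_a <- fwd(mm$atac$params, xa, cva$te, cva$cond, cva$batch)
  expect_equal(L$loss_align, mean((m_a - m_r)^2), tolerance = 1e-6)
  dec_p <- function(p, z, te, cond, bat) {
    th <- pmax(sweep(te %*% p$dec$time$W, 2, p$dec$time$b, "+"), 0)
    h <- cbind(z, th, cond, bat)
    for (l in p$dec$trunk) h <- pmax(sweep(h %*% l$W, 2, l$b, "+"), 0)
    1 / (1 + exp(-sweep(h %*% p$dec$scale$W, 2, p$dec$scale$b, "+")))
  }
  p_ab <- dec_p(mm$atac$params, m_r, cva$te, cva$cond, cva$batch)
  expect_equal(L$loss_trans_ab, mean(-rowSums(bernoulli_loglik(xa, p_ab))),
               tolerance = 1e-6)
  # identical paired embeddings give zero alignment loss
  expect_equal(mean((m_r - m_r)^2), 0)
})

test_that("stepwise training shares and freezes the time layer and is deterministic", {
  sim <- micro_sim()
  mm <- micro_mm_model()
  expect_identical(mm$rna$params$dec$time, mm$atac$params$dec$time)
  splits <- make_splits(sim$data, split_spec(seed = 1))
  mm2 <- train_multimodal(sim$data, splits, micro_config(seed = 1),
                          lambda_mse = 100)
  expect_identical(mm$history, mm2$history)
  expect_identical(mm$atac$params, mm2$atac$params)
  # pairing is required
  nopair <- sim$data
  nopair$cells$pair_id <- NA_character_
  expect_error(train_multimodal(nopair, splits, micro_config(seed = 1)),
               "pair")
})

test_that("co-assay pairs embed closer than random cross-modality pairs", {
  sim <- micro_sim()
  mm <- micro_mm_model()
  pairs <- coassay_pairs(sim$data)
  emb <- cell_embeddings(mm, sim$data)
  ids <- sim$data$cells$cell_id
  d_pair <- sqrt(rowSums((emb[ids[pairs[, 1]], ] - emb[ids[pairs[, 2]], ])^2))
  set.seed(1)
  d_rand <- sqrt(rowSums((emb[ids[pairs[, 1]], ] -
                            emb[ids[sample(pairs[, 2])], ])^2))
  expect_lt(mean(d_pair), mean(d_rand))
})

test_that("cross-modal translation beats an untrained model on pseudobulk", {
  sim <- micro_sim()
  mm <- micro_mm_model()
  splits <- make_splits(sim$data, split_spec(seed = 1))
  untrained <- train_multimodal(sim$data, splits,
                                micro_config(seed = 1, max_epochs = 1L,
                                             learning_rate = 0, kl_warmup = 0L),
                                lambda_mse = 100)
  cells <- sim$data$cells
  atac_cols <- mm$atac$feature_cols
  cors <- vapply(list(mm, untrained), function(model) {
    r <- vapply(sort(unique(cells$cell_type)), function(ct) {
      rna_q <- which(cells$modality == "RNA" & cells$cell_type == ct)[1:20]
      truth_cells <- which(cells$modality == "ATAC" & cells$cell_type == ct)
      tp <- cells$time_days[rna_q[1]]
      pred <- predict_profiles(model, sim$data, rna_q, target_time = tp,
                               target_modality = "ATAC")
      truth <- colMeans(as.matrix(sim$data$counts[truth_cells, atac_cols]))
      cor(colMeans(pred), truth)
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_gt(cors[1], 0)
  expect_gt(cors[1], cors[2])
})
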