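test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_multiomic_timeseries(micro_spec())
  b <- simulate_multiomic_timeseries(micro_spec())
  expect_identical(as.matrix(a$data$counts), as.matrix(b$data$counts))
  expect_identical(a$data$cells, b$data$cells)
  expect_identical(a$truth$genes, b$truth$genes)
  c2 <- simulate_multiomic_timeseries(micro_spec(seed = 8))
  expect_false(identical(as.matrix(a$data$counts), as.matrix(c2$data$counts)))
})

test_that("the generator writes a valid multi-omic dataset with planted truth", {
  sim <- micro_sim()
  d <- sim$data
  expect_s3_class(d, "timeseries_dataset")
  expect_setequal(unique(d$cells$modality), c("RNA", "ATAC"))
  # ATAC block is binary; RNA block is counts
  atac_rows <- d$cells$modality == "ATAC"
  atac_cols <- d$features$modality == "ATAC"
  expect_true(all(as.matrix(d$counts[atac_rows, atac_cols]) %in% c(0, 1)))
  expect_equal(sum(d$counts[atac_rows, !atac_cols]), 0)
  # co-assay pairs link one RNA to one ATAC cell
  pairs <- coassay_pairs(d)
  expect_gt(nrow(pairs), 0)
  expect_equal(d$cells$pair_id[pairs[, 1]], d$cells$pair_id[pairs[, 2]])
  expect_true(all(d$cells$modality[pairs[, 1]] == "RNA"))
  # planted lags lie in the configured range with both signs represented
  expect_true(all(abs(sim$truth$pairs$tau) >= 0.1 - 1e-9 &
                    abs(sim$truth$pairs$tau) <= 0.2 + 1e-9))
  # every sex-masked time point carries at least one sex
  expect_true(all(table(d$cells$time_days) > 0))
})

test_that("empirical ZINB zero fraction matches the mixture formula", {
  set.seed(20)
  n <- 1e4
  for (ps in list(c(mu = 2, theta = 1, pi = 0.2),
                  c(mu = 8, theta = 0.6, pi = 0),
                  c(mu = 0.7, theta = 3, pi = 0.4))) {
    x <- rnbinom(n, size = ps["theta"], mu = ps["mu"]) *
      (1 - rbinom(n, 1, ps["pi"]))
    p0 <- ps["pi"] + (1 - ps["pi"]) *
      (ps["theta"] / (ps["theta"] + ps["mu"]))^ps["theta"]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(x == 0) - p0), 3 * se + 1e-3)
  }
})

test_that("planted sex effects reach the expected pseudobulk fold change", {
  sim <- tiny_sim()
  d <- sim$data; gt <- sim$truth$genes
  rna_cols <- which(d$features$modality == "RNA")
  f_cells <- which(d$cells$modality == "RNA" & d$cells$condition == "F")
  m_cells <- which(d$cells$modality == "RNA" & d$cells$condition == "M")
  pb_f <- pseudobulk_profile(d$counts[f_cells, rna_cols])
  pb_m <- pseudobulk_profile(d$counts[m_cells, rna_cols])
  up <- which(gt$sex_logfc > 0)
  # planted natural-log FC of +1 => fold change near e, within the
  # tolerance band that also absorbs time/composition confounding
  fc <- pb_f[up] / pb_m[up]
  expect_gt(mean(fc >= 1.6 & fc <= 3.4), 0.7)
  expect_gt(median(fc), 1.6); expect_lt(median(fc), 3.4)
  # null genes show no consistent shift
  null <- which(gt$sex_logfc == 0)
  expect_lt(abs(median(log(pb_f[null] / pb_m[null]))), 0.2)
})

test_that("null genes score near 0.5 on observed single-cell differences", {
  sim <- tiny_sim()
  d <- sim$data; gt <- sim$truth$genes
  rna_cols <- which(d$features$modality == "RNA")
  # paired F/M comparison at a doubly-profiled time point, same cell type
  tp <- 8.25
  f <- which(d$cells$modality == "RNA" & d$cells$condition == "F" &
               d$cells$time_days == tp & d$cells$cell_type == "type1")
  m <- which(d$cells$modality == "RNA" & d$cells$condition == "M" &
               d$cells$time_days == tp & d$cells$cell_type == "type1")
  n <- min(length(f), length(m))
  # the default mask doubly profiles every third time point
  expect_gte(n, 20)
  xf <- as.matrix(d$counts[f[1:n], rna_cols]); xf <- xf / rowSums(xf)
  xm <- as.matrix(d$counts[m[1:n], rna_cols]); xm <- xm / rowSums(xm)
  null <- which(gt$sex_logfc == 0)
  sc <- apply(xf[, null] - xm[, null], 2, signed_rank_score)
  expect_gt(mean(sc > 0.35 & sc < 0.65, na.rm = TRUE), 0.8)
})

test_that("planted lags are recoverable from noiseless generator trajectories", {
  sim <- micro_sim()
  gt <- sim$truth$genes; gtp <- sim$truth$pairs
  tg <- seq(7.5, 9, by = 0.01)
  g <- match(gtp$gene_id, gt$gene_id)
  for (j in seq_len(nrow(gtp))) {
    f <- temporal_program_value(gt$family[g[j]], gt$amplitude[g[j]],
                                gt$center[g[j]], gt$period[g[j]], tg)
    acc <- pmin(pmax(0.5 + gtp$coupling[j] *
                       temporal_program_value(gt$family[g[j]], gt$amplitude[g[j]],
                                              gt$center[g[j]], gt$period[g[j]],
                                              tg + gtp$tau[j]) /
                       abs(gt$amplitude[g[j]]), 0.02), 0.98)
    expr <- if (gtp$coupling[j] < 0) -f else f
    tv <- tlcc_vector(tg, expr, acc)
    expect_lte(abs(tv$best_shift - gtp$tau[j]), 0.01 + 1e-9)
  }
})

test_that("tiny and desk presets share planted-effect definitions", {
  tiny <- default_acceptance_spec("tiny")
  desk <- default_acceptance_spec("desk")
  expect_equal(tiny$lag_range, desk$lag_range)
  expect_equal(tiny$sex_logfc, desk$sex_logfc)
  expect_equal(tiny$n_escape_genes, desk$n_escape_genes)
  expect_gt(desk$genes, tiny$genes)
  expect_gt(desk$n_cell_types, tiny$n_cell_types)
})
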