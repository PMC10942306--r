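test_that("peak-gene mapping uses strand-aware upstream windows", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          tss = c(500000L, 500000L), strand = c("+", "-"))
  peaks <- tibble::tibble(
    peak_id = c("up_plus", "down_plus", "down_minus", "far"),
    chrom = "chr1",
    start = c(400000L, 550000L, 600000L, 2000000L),
    end = c(400500L, 550500L, 600500L, 2000500L))
  m <- map_peaks_to_genes(peaks, genes)
  expect_true(any(m$peak_id == "up_plus" & m$gene_id == "gp"))
  expect_false(any(m$peak_id == "down_plus" & m$gene_id == "gp"))
  expect_true(any(m$peak_id == "down_minus" & m$gene_id == "gm"))
  expect_false(any(m$peak_id == "far"))
  genes$strand[1] <- NA
  expect_error(map_peaks_to_genes(peaks, genes), "strand")
})

test_that("TLCC vector has 101 shifts and recovers analytic lags", {
  tg <- seq(7.5, 9, by = 0.01)
  expr <- sin(2 * pi * tg)
  # accessibility leading expression by 0.2 day
  acc <- sin(2 * pi * (tg + 0.2))
  tv <- tlcc_vector(tg, expr, acc)
  expect_length(tv$corr, 101L)
  expect_equal(tv$shifts, seq(-0.5, 0.5, by = 0.01))
  expect_equal(tv$best_shift, 0.20)
  # identical trajectories: zero shift, perfect correlation
  tv0 <- tlcc_vector(tg, expr, expr)
  expect_equal(tv0$best_shift, 0)
  expect_equal(tv0$max_corr, 1)
  # constant trajectory: missing correlations
  tvc <- tlcc_vector(tg, expr, rep(1, length(tg)))
  expect_true(all(is.na(tvc$corr)))
  expect_true(is.na(tvc$best_shift))
  expect_error(tlcc_vector(tg[c(1, 3, 9)], expr[c(1, 3, 9)], acc[c(1, 3, 9)]),
               "evenly spaced")
})

test_that("TLCC recovers noiseless lags within one step across [-0.4, 0.4]", {
  tg <- seq(7.5, 9, by = 0.01)
  base <- function(t) sin(2 * pi * t / 1.3) + 0.4 * cos(2 * pi * t / 0.9)
  for (tau in seq(-0.4, 0.4, by = 0.05)) {
    tv <- tlcc_vector(tg, base(tg), base(tg + tau))
    expect_lte(abs(tv$best_shift - tau), 0.01 + 1e-9)
  }
  # antisymmetry: swapping which trajectory is shifted negates the lag
  tv_f <- tlcc_vector(tg, base(tg), base(tg + 0.15))
  tv_r <- tlcc_vector(tg, base(tg + 0.15), base(tg))
  expect_equal(tv_f$best_shift, -tv_r$best_shift)
})

test_that("lag-direction classification requires unanimity across cells", {
  mk <- function(shifts_by_cell) {
    cols <- tibble::tibble(
      peak_id = "p1", gene_id = "g1",
      cell = paste0("c", seq_along(shifts_by_cell)),
      best_shift = shifts_by_cell, max_corr = 0.9,
      n_cells = length(shifts_by_cell))
    structure(list(shifts = seq(-0.5, 0.5, 0.01),
                   corr = matrix(0, 101, length(shifts_by_cell)),
                   columns = cols),
              class = "tlcc_matrix")
  }
  expect_equal(classify_lag_direction(mk(c(0.1, 0.2)))$category, "before")
  expect_equal(classify_lag_direction(mk(c(-0.1, -0.3)))$category, "after")
  expect_equal(classify_lag_direction(mk(c(0.1, -0.1)))$category, "unclassified")
})

test_that("TLCC matrix applies the correlation and multiplicity filters", {
  sim <- micro_sim()
  mm <- micro_mm_model()
  cells <- sim$data$cells
  rna_ids <- cells$cell_id[cells$modality == "RNA"]
  q <- rna_ids[1]
  pairs <- sim$truth$pairs[1:4, c("peak_id", "gene_id")]
  tm <- tlcc_matrix(mm, sim$data, q, rna_ids[2:3], pairs,
                    time_grid = seq(7.5, 9, 0.01))
  if (nrow(tm$columns) > 0) {
    expect_true(all(tm$columns$max_corr >= 0.5))
    expect_true(all(tm$columns$n_cells > 1))
    expect_equal(ncol(tm$corr), nrow(tm$columns))
    expect_equal(nrow(tm$corr), 101L)
    cls <- classify_lag_direction(tm)
    expect_true(all(cls$category %in% c("before", "after", "unclassified")))
  }
  # an impossible correlation threshold removes everything, with a warning
  expect_warning(
    empty <- tlcc_matrix(mm, sim$data, q, rna_ids[2:3], pairs,
                         time_grid = seq(7.5, 9, 0.01), min_corr = 1.01),
    "filter")
  expect_equal(ncol(empty$corr), 0L)
})
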