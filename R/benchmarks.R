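# Validation experiments on synthetic data with planted ground truth.
# Each experiment is deterministic given its seeds and returns the tidy
# quantities the package's validation story rests on; the test suite and
# scripts/acceptance.R both run these.

#' Study-scale model configuration for the validation experiments
#'
#' The configuration used by the package's synthetic validation runs:
#' latent dimension 16 and hidden width 128 (scaled to the tiny study
#' conditions), 50-dimensional time encoding, up to 100 epochs with
#' early-stopping patience 12.
#'
#' @param seed Training seed.
#' @param min_wavelength Minimum wavelength of the time encoding (days).
#' @param max_epochs,patience Training-length overrides.
#' @return A [model_config()].
#' @export
benchmark_config <- function(seed, min_wavelength = 1,
                             max_epochs = 100L, patience = 12L) {
  model_config(latent_dim = 16L, hidden_width = 128L,
               time_cfg = time_encoding_config(d = 50L,
                                               min_wavelength = min_wavelength),
               max_epochs = max_epochs, patience = patience,
               batch_size = 256L, seed = seed)
}

#' Cross-time imputation versus the neighbouring-time baseline
#'
#' For each model seed, one interior time point is held out, a model is
#' trained on the rest, and [evaluate_cross_time()] compares the model's
#' held-out-time pseudobulk predictions against the neighbouring-time
#' baseline from both sides.
#'
#' @param sim Output of [simulate_multiomic_timeseries()].
#' @param seeds Integer vector of model seeds (one model per seed).
#' @param config_fn Function `seed -> model_config`; defaults to
#'   [benchmark_config()] at an 80-epoch budget.
#' @return List with `results` (tibble over cell type x side x seed),
#'   `frac_beat_baseline`, and `models` (the trained ensemble, each with a
#'   `held_out_time` attribute).
#' @export
benchmark_cross_time <- function(sim, seeds = 1:3,
                                 config_fn = function(s)
                                   benchmark_config(s, max_epochs = 80L,
                                                    patience = 10L)) {
  data <- sim$data
  tps <- sort(unique(data$cells$time_days))
  interior <- tps[-c(1, length(tps))]
  models <- list(); rows <- list()
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    ho <- interior[1 + (i - 1) %% length(interior)]
    splits <- make_splits(data, split_spec(held_out_time = ho, seed = s))
    m <- train_single_modality(data, splits, config_fn(s))
    attr(m, "held_out_time") <- ho
    models[[i]] <- m
    for (side in c("previous", "subsequent")) {
      ev <- evaluate_cross_time(m, data, held_out_time = ho, query_side = side)
      if (nrow(ev) > 0) {
        ev$seed <- s
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  list(results = results,
       frac_beat_baseline = mean(results$prediction_score >
                                   results$baseline_score),
       models = models)
}

#' Sex-bias score ranking of planted escape-like genes
#'
#' Computes the ensemble sex-bias table and the AUROC of the mean per-gene
#' score for planted always-female-biased genes against other genes on the
#' same chromosome (chrX), plus the AUROC over all planted female-biased
#' genes versus all autosomal nulls.
#'
#' @param sim Output of [simulate_multiomic_timeseries()].
#' @param models Trained RNA ensemble (e.g. from [benchmark_cross_time()]).
#' @return List with `escape_auroc`, `female_auroc` and the `table`.
#' @export
benchmark_sexbias <- function(sim, models) {
  tab <- compute_sexbias_table(models, sim$data)
  gt <- sim$truth$genes
  gs <- tab |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::left_join(gt, by = c(gene = "gene_id"))
  chrx <- dplyr::filter(gs, .data$chrom == "chrX")
  list(escape_auroc = auroc(chrx$score, chrx$is_escape),
       female_auroc = auroc(gs$score, gs$sex_logfc > 0),
       table = tab)
}

# planted probability-scale change of coupled peaks between two times
planted_peak_delta <- function(truth, t1, t2) {
  gt <- truth$genes; pr <- truth$pairs
  g <- match(pr$gene_id, gt$gene_id)
  vapply(seq_len(nrow(pr)), function(j) {
    f <- function(t) temporal_program_value(gt$family[g[j]], gt$amplitude[g[j]],
                                            gt$center[g[j]], gt$period[g[j]], t)
    pr$coupling[j] * (f(t2 + pr$tau[j]) - f(t1 + pr$tau[j])) / abs(gt$amplitude[g[j]])
  }, numeric(1))
}

#' Cross-modal recovery of the planted direction of accessibility change
#'
#' For each seed, all ATAC cells at one interior time point are held out, a
#' multimodal model is trained on the rest, and RNA cells at the
#' neighbouring time point are used to predict per-peak accessibility at
#' both times. The per-peak signed-rank direction score is compared with
#' the planted direction of change for coupled peaks whose planted
#' probability change exceeds `min_delta`.
#'
#' @param sim Output of [simulate_multiomic_timeseries()].
#' @param seeds Integer vector of model seeds.
#' @param min_delta Minimum planted probability change for a peak to count
#'   as changing (default 0.1).
#' @param config_fn Function `seed -> model_config`.
#' @return List with `frac_direction_correct`, `n_changing` and the
#'   per-seed `results` tibble.
#' @export
benchmark_cross_modal <- function(sim, seeds = 1:3, min_delta = 0.1,
                                  config_fn = function(s)
                                    benchmark_config(s, max_epochs = 80L,
                                                     patience = 10L)) {
  data <- sim$data
  cells <- data$cells
  tps <- sort(unique(cells$time_days))
  interior <- tps[-c(1, length(tps))]
  atac_ids <- get_feature_ids(data, "ATAC")
  rows <- list()
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    ho <- interior[1 + (i - 1) %% length(interior)]
    query_t <- tps[match(ho, tps) - 1]
    sp <- make_splits(data, split_spec(seed = s))
    ho_atac <- which(cells$modality == "ATAC" & cells$time_days == ho)
    sp$train <- setdiff(sp$train, ho_atac)
    sp$val <- setdiff(sp$val, ho_atac)
    sp$test <- sort(union(sp$test, ho_atac))
    mm <- train_multimodal(data, sp, config_fn(s), lambda_mse = 100)
    q <- which(cells$modality == "RNA" & cells$time_days == query_t)
    q <- q[seq_len(min(length(q), 200L))]
    pred_ho <- predict_profiles(mm, data, q, target_time = ho,
                                target_modality = "ATAC")
    pred_q <- predict_profiles(mm, data, q, target_time = query_t,
                               target_modality = "ATAC")
    dds <- differential_direction_score(pred_q, pred_ho)
    delta <- planted_peak_delta(sim$truth, query_t, ho)
    cols <- match(sim$truth$pairs$peak_id, colnames(pred_ho))
    keep <- abs(delta) > min_delta
    rows[[i]] <- tibble(seed = s, held_out_time = ho,
                        peak_id = sim$truth$pairs$peak_id[keep],
                        planted_delta = delta[keep],
                        direction_score = dds[cols[keep]])
  }
  results <- dplyr::bind_rows(rows)
  ok <- sign(results$direction_score - 0.5) == sign(results$planted_delta)
  list(frac_direction_correct = mean(ok, na.rm = TRUE),
       n_changing = nrow(results), results = results)
}

get_feature_ids <- function(data, modality) {
  if ("modality" %in% names(data$features)) {
    data$features$feature_id[data$features$modality == modality]
  } else data$features$feature_id
}

#' Lag-sign recovery of planted peak-gene couplings via TLCC
#'
#' Trains a multimodal ensemble on the full time series (smooth
#' time-encoding basis), predicts expression and accessibility trajectories
#' for a query cell and its nearest neighbours, and compares the recovered
#' best shift of every surviving planted pair with the planted lag sign.
#'
#' @param sim Output of [simulate_multiomic_timeseries()].
#' @param seeds Integer vector of model seeds for the ensemble.
#' @param n_query Number of query cells (their TLCC matrices are pooled;
#'   default 1).
#' @param config_fn Function `seed -> model_config`; defaults to
#'   [benchmark_config()] with the smooth (`2 * pi`) minimum wavelength.
#' @return List with `frac_sign_correct` (surviving pairs whose median
#'   best shift matches the planted lag sign), `n_surviving`,
#'   `classification` and the underlying `columns` tibble.
#' @export
benchmark_tlcc <- function(sim, seeds = 1:3, n_query = 1L,
                           config_fn = function(s)
                             benchmark_config(s, min_wavelength = 2 * pi,
                                              max_epochs = 120L,
                                              patience = 15L)) {
  data <- sim$data
  cells <- data$cells
  mms <- lapply(seeds, function(s) {
    train_multimodal(data, make_splits(data, split_spec(seed = s)),
                     config_fn(s), lambda_mse = 100)
  })
  rna_idx <- which(cells$modality == "RNA")
  emb <- cell_embeddings(mms[[1]], data, rna_idx)
  mid_t <- sort(unique(cells$time_days))[3]
  qs <- cells$cell_id[which(cells$modality == "RNA" &
                              cells$time_days == mid_t)][seq_len(n_query)]
  pairs <- sim$truth$pairs[, c("peak_id", "gene_id")]
  cols <- list()
  for (q in qs) {
    nb <- aggregate_neighbors(list(emb), q)
    tm <- tlcc_matrix(mms, data, q, nb, pairs)
    if (nrow(tm$columns) > 0) cols[[length(cols) + 1L]] <- tm$columns
  }
  columns <- dplyr::bind_rows(cols)
  if (nrow(columns) == 0L) {
    return(list(frac_sign_correct = NA_real_, n_surviving = 0L,
                classification = tibble(), columns = columns))
  }
  per_pair <- columns |>
    dplyr::group_by(.data$peak_id, .data$gene_id) |>
    dplyr::summarise(median_shift = median(.data$best_shift),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(sim$truth$pairs, by = c("peak_id", "gene_id"))
  cls <- columns |>
    dplyr::group_by(.data$peak_id, .data$gene_id) |>
    dplyr::summarise(category = if (all(.data$best_shift > 0)) "before"
                     else if (all(.data$best_shift < 0)) "after"
                     else "unclassified", .groups = "drop")
  list(frac_sign_correct = mean(sign(per_pair$median_shift) ==
                                  sign(per_pair$tau)),
       n_surviving = nrow(per_pair),
       classification = cls, columns = columns, models = mms)
}

#' Adversarial disentanglement of time from cell identity
#'
#' For each seed, two models are trained on identical data and seed, one
#' with the adversary enabled and one without; a freshly trained
#' multinomial-logistic probe then predicts each cell's observed time point
#' from its embedding. Disentanglement succeeds when the probe is less
#' accurate (and the time-mixing LISI higher) on adversarial embeddings.
#'
#' @param sim Output of [simulate_multiomic_timeseries()].
#' @param seeds Integer vector of seeds.
#' @param max_epochs Training length per arm (default 40).
#' @return Tibble with one row per seed: probe accuracies and mean time
#'   LISI for both arms.
#' @export
benchmark_disentanglement <- function(sim, seeds = 1:3, max_epochs = 40L) {
  data <- sim$data
  splits <- make_splits(data, split_spec(seed = seeds[1]))
  rna_tr <- intersect(splits$train, which(data$cells$modality == "RNA"))
  rna_va <- intersect(splits$val, which(data$cells$modality == "RNA"))
  probe_acc <- function(model) {
    emb_tr <- cell_embeddings(model, data, rna_tr)
    emb_te <- cell_embeddings(model, data, rna_va)
    df_tr <- data.frame(y = factor(data$cells$time_days[rna_tr]), emb_tr)
    fit <- nnet::multinom(y ~ ., df_tr, trace = FALSE, MaxNWts = 5000)
    pred <- predict(fit, data.frame(emb_te))
    mean(as.character(pred) == as.character(data$cells$time_days[rna_va]))
  }
  time_lisi <- function(model) {
    lisi_score(cell_embeddings(model, data, rna_va),
               data$cells$time_days[rna_va])$mean
  }
  purrr::map_dfr(seeds, function(s) {
    cfg <- benchmark_config(s, max_epochs = max_epochs,
                            patience = max_epochs)
    cfg_off <- cfg; cfg_off$adversary <- FALSE
    m_adv <- train_single_modality(data, splits, cfg)
    m_off <- train_single_modality(data, splits, cfg_off)
    tibble(seed = s,
           probe_acc_adversary = probe_acc(m_adv),
           probe_acc_no_adversary = probe_acc(m_off),
           lisi_adversary = time_lisi(m_adv),
           lisi_no_adversary = time_lisi(m_off))
  })
}
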