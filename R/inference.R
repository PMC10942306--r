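# Factor-swapping inference: encode a cell under its observed covariates,
# decode under a target time / condition / modality.

get_branch <- function(model, modality) {
  if (inherits(model, "chronocell_mm_model")) {
    switch(modality, RNA = model$rna, ATAC = model$atac,
           abort(paste0("Unknown modality: ", modality)))
  } else if (inherits(model, "chronocell_model")) {
    if (model$modality != modality) {
      abort(sprintf("Model has no %s branch (single-modality %s model).",
                    modality, model$modality))
    }
    model
  } else abort("Not a chronocell model.")
}

resolve_cells <- function(data, cells) {
  if (is.character(cells)) {
    idx <- match(cells, data$cells$cell_id)
    if (any(is.na(idx))) abort("Unknown cell id(s).")
    idx
  } else as.integer(cells)
}

#' Predict denoised profiles for a set of cells under target factors
#'
#' Each query cell is encoded with its *own* observed time, condition and
#' batch (posterior mean, no sampling), then decoded with the target time
#' encoding, the target condition one-hot and a caller-chosen reference
#' batch. RNA outputs are depth-normalised expected proportions (each row
#' sums to 1); ATAC outputs are per-peak accessibility probabilities in
#' `[0, 1]`. Fully deterministic.
#'
#' @param model A `chronocell_model` or `chronocell_mm_model`.
#' @param data The [timeseries_dataset()] the query cells come from.
#' @param cells Cell indices or cell ids (all of one modality).
#' @param target_time Target time in days (scalar).
#' @param target_condition Target condition level; default: each cell's own.
#' @param target_modality `"RNA"` or `"ATAC"`; default: the query modality.
#' @param reference_batch Batch level used at decode time; default: first
#'   batch level of the model.
#' @return Matrix, cells x target-modality features.
#' @export
predict_profiles <- function(model, data, cells, target_time,
                             target_condition = NULL, target_modality = NULL,
                             reference_batch = NULL) {
  idx <- resolve_cells(data, cells)
  qmod <- unique(data$cells$modality[idx])
  if (length(qmod) != 1L) abort("Query cells must share one modality.")
  enc_branch <- get_branch(model, qmod)
  target_modality <- target_modality %||% qmod
  dec_branch <- get_branch(model, target_modality)
  if (!is.null(target_condition) &&
      !target_condition %in% dec_branch$condition_levels) {
    abort(paste0("Unknown condition level: ", target_condition,
                 " (known: ", paste(dec_branch$condition_levels, collapse = ", "), ")"))
  }
  reference_batch <- reference_batch %||% dec_branch$batch_levels[1]
  cols <- enc_branch$feature_cols %||% seq_len(ncol(data$counts))
  x <- as.matrix(data$counts[idx, cols, drop = FALSE])
  x_in <- if (qmod == "RNA") log1p(x) else x
  cv <- model_covariates(enc_branch, data$cells$time_days[idx],
                         data$cells$condition[idx], data$cells$batch[idx])
  enc <- branch_encode(enc_branch$params, x_in, cv$te, cv$cond, cv$batch)
  n <- length(idx)
  te_t <- sinusoidal_encode(rep(target_time, n), dec_branch$config$time_cfg)
  cond_t <- encode_categories(
    if (is.null(target_condition)) data$cells$condition[idx]
    else rep(target_condition, n),
    dec_branch$condition_levels)
  batch_t <- encode_categories(rep(reference_batch, n), dec_branch$batch_levels)
  if (target_modality == "RNA") {
    dec <- branch_decode(dec_branch$params, enc$mean, te_t, cond_t, batch_t,
                         "zinb", lib = NULL)
    out <- dec$rho
  } else {
    dec <- branch_decode(dec_branch$params, enc$mean, te_t, cond_t, batch_t,
                         "bernoulli")
    out <- dec$p
  }
  rownames(out) <- data$cells$cell_id[idx]
  colnames(out) <- dec_branch$feature_ids
  out
}

#' Predict one cell's denoised profile under target factors
#'
#' Single-cell wrapper around [predict_profiles()].
#'
#' @inheritParams predict_profiles
#' @param cell One cell index or id.
#' @return A `predicted_profile`: list with `values` (named numeric vector),
#'   `query_cell`, `target_time`, `target_condition`, `target_modality`.
#' @export
predict_profile <- function(model, data, cell, target_time,
                            target_condition = NULL, target_modality = NULL,
                            reference_batch = NULL) {
  idx <- resolve_cells(data, cell)
  stopifnot(length(idx) == 1L)
  m <- predict_profiles(model, data, idx, target_time, target_condition,
                        target_modality, reference_batch)
  structure(list(values = m[1, ],
                 query_cell = data$cells$cell_id[idx],
                 target_time = target_time,
                 target_condition = target_condition %||% data$cells$condition[idx],
                 target_modality = target_modality %||% data$cells$modality[idx]),
            class = "predicted_profile")
}

#' @export
print.predicted_profile <- function(x, ...) {
  cat(sprintf("<predicted_profile> cell %s at day %.3g (%s, %s): %d features\n",
              x$query_cell, x$target_time, x$target_condition,
              x$target_modality, length(x$values)))
  invisible(x)
}

#' @export
tidy.predicted_profile <- function(x, ...) {
  tibble(feature_id = names(x$values), value = unname(x$values),
         query_cell = x$query_cell, target_time = x$target_time,
         target_condition = x$target_condition,
         target_modality = x$target_modality)
}

#' Predict one cell's trajectory over a time grid
#'
#' @inheritParams predict_profile
#' @param time_grid Increasing numeric vector of times (days).
#' @return Matrix, `length(time_grid)` x features, with times as rownames.
#' @export
predict_trajectory <- function(model, data, cell, time_grid,
                               target_condition = NULL, target_modality = NULL,
                               reference_batch = NULL) {
  if (length(time_grid) == 0L) abort("`time_grid` must be nonempty.")
  if (any(!is.finite(time_grid)) || is.unsorted(time_grid)) {
    abort("`time_grid` must be finite and increasing.")
  }
  idx <- resolve_cells(data, cell)
  stopifnot(length(idx) == 1L)
  qmod <- data$cells$modality[idx]
  enc_branch <- get_branch(model, qmod)
  target_modality <- target_modality %||% qmod
  dec_branch <- get_branch(model, target_modality)
  reference_batch <- reference_batch %||% dec_branch$batch_levels[1]
  cols <- enc_branch$feature_cols %||% seq_len(ncol(data$counts))
  x <- as.matrix(data$counts[idx, cols, drop = FALSE])
  x_in <- if (qmod == "RNA") log1p(x) else x
  cv <- model_covariates(enc_branch, data$cells$time_days[idx],
                         data$cells$condition[idx], data$cells$batch[idx])
  enc <- branch_encode(enc_branch$params, x_in, cv$te, cv$cond, cv$batch)
  n <- length(time_grid)
  z <- matrix(enc$mean, n, ncol(enc$mean), byrow = TRUE)
  te_t <- sinusoidal_encode(time_grid, dec_branch$config$time_cfg)
  cond_t <- encode_categories(
    rep(target_condition %||% data$cells$condition[idx], n),
    dec_branch$condition_levels)
  batch_t <- encode_categories(rep(reference_batch, n), dec_branch$batch_levels)
  out <- if (target_modality == "RNA") {
    branch_decode(dec_branch$params, z, te_t, cond_t, batch_t, "zinb")$rho
  } else {
    branch_decode(dec_branch$params, z, te_t, cond_t, batch_t, "bernoulli")$p
  }
  rownames(out) <- format(time_grid, trim = TRUE)
  colnames(out) <- dec_branch$feature_ids
  out
}

#' Element-wise median prediction across an ensemble of models
#'
#' @param models List of trained models sharing the target feature space.
#' @param ... Arguments passed to [predict_profiles()] (`data`, `cells`,
#'   `target_time`, ...).
#' @return Matrix like [predict_profiles()], the per-entry median across
#'   models.
#' @export
ensemble_median <- function(models, ...) {
  stopifnot(length(models) >= 1L)
  preds <- lapply(models, function(m) predict_profiles(m, ...))
  f1 <- colnames(preds[[1]])
  for (p in preds) {
    if (!identical(colnames(p), f1)) abort("Models do not share a feature space.")
  }
  if (length(preds) == 1L) return(preds[[1]])
  arr <- array(unlist(preds), dim = c(dim(preds[[1]]), length(preds)))
  out <- apply(arr, c(1, 2), median)
  dimnames(out) <- dimnames(preds[[1]])
  out
}

#' Posterior-mean cell embeddings
#'
#' @param model A trained model.
#' @param data The [timeseries_dataset()].
#' @param cells Cell indices or ids; default all cells of modalities the
#'   model covers.
#' @return Matrix, cells x latent dims, rownames = cell ids.
#' @export
cell_embeddings <- function(model, data, cells = NULL) {
  if (is.null(cells)) {
    mods <- if (inherits(model, "chronocell_mm_model")) c("RNA", "ATAC")
    else model$modality
    cells <- which(data$cells$modality %in% mods)
  }
  idx <- resolve_cells(data, cells)
  out <- NULL
  for (mod in unique(data$cells$modality[idx])) {
    sub <- idx[data$cells$modality[idx] == mod]
    br <- get_branch(model, mod)
    cols <- br$feature_cols %||% seq_len(ncol(data$counts))
    x <- as.matrix(data$counts[sub, cols, drop = FALSE])
    x_in <- if (mod == "RNA") log1p(x) else x
    cv <- model_covariates(br, data$cells$time_days[sub],
                           data$cells$condition[sub], data$cells$batch[sub])
    m <- branch_encode(br$params, x_in, cv$te, cv$cond, cv$batch)$mean
    rownames(m) <- data$cells$cell_id[sub]
    out <- rbind(out, m)
  }
  out[match(data$cells$cell_id[idx], rownames(out)), , drop = FALSE]
}

#' Consensus nearest neighbours across an ensemble of embeddings
#'
#' Per model, candidate cells are ranked by Euclidean distance to the query
#' and the top `k_list` kept; cells absent from any model's top list are
#' excluded; ranks are summed across models and the `k_keep` cells with the
#' smallest summed rank returned (ties broken by cell-id sort order).
#'
#' @param per_model_embeddings List of embedding matrices (cells x dims,
#'   rownames = cell ids), one per model; all must contain the query.
#' @param query_cell Cell id (rowname) of the query.
#' @param k_list Per-model shortlist size (default 25).
#' @param k_keep Number of neighbours returned (default 4).
#' @return Character vector of neighbour cell ids (without the query). If
#'   fewer than `k_keep` candidates survive, all survivors are returned with
#'   a warning.
#' @export
aggregate_neighbors <- function(per_model_embeddings, query_cell,
                                k_list = 25L, k_keep = 4L) {
  stopifnot(length(per_model_embeddings) >= 1L)
  rank_tabs <- lapply(per_model_embeddings, function(E) {
    if (!query_cell %in% rownames(E)) abort("Query cell missing from an embedding.")
    q <- E[query_cell, ]
    cand <- setdiff(rownames(E), query_cell)
    d <- sqrt(rowSums((E[cand, , drop = FALSE] -
                         matrix(q, length(cand), length(q), byrow = TRUE))^2))
    r <- rank(d, ties.method = "first")
    keep <- r <= k_list
    setNames(r[keep], cand[keep])
  })
  common <- Reduce(intersect, lapply(rank_tabs, names))
  if (length(common) == 0L) {
    warn("No candidate survives in every model's shortlist.")
    return(character(0))
  }
  rank_sum <- Reduce(`+`, lapply(rank_tabs, function(r) r[common]))
  ord <- order(rank_sum, common)
  out <- common[ord]
  if (length(out) < k_keep) {
    warn(sprintf("Only %d candidate(s) survive; returning all.", length(out)))
    return(out)
  }
  out[seq_len(k_keep)]
}
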