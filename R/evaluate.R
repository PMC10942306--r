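#' Cross-time (and cross-condition) pseudobulk evaluation
#'
#' For each cell type with at least `min_cells` cells at the held-out time
#' point, query cells of that type are taken from the neighbouring time
#' point on the requested side (optionally from the opposite condition),
#' their profiles are predicted at the held-out time, and the pseudobulk of
#' the predictions is correlated (Pearson) with the held-out truth
#' pseudobulk. The baseline is the depth-normalised pseudobulk of the query
#' time point itself, or the mean of the previous- and subsequent-time
#' pseudobulks. A one-sided paired signed-rank p-value across cell types
#' (prediction beats baseline) is attached as attribute `p_value`.
#'
#' Cell-type labels are used for evaluation only; the model never sees
#' them.
#'
#' @param model A trained model (or list of models, ensembled by
#'   [ensemble_median()]).
#' @param data The full [timeseries_dataset()] including held-out cells.
#' @param held_out_time Held-out time point (must exist in `data`).
#' @param held_out_condition Optional condition of the held-out population.
#' @param query_side `"previous"` or `"subsequent"`.
#' @param condition_mode `"same"` or `"opposite"` (swap sex at prediction).
#' @param baseline_mode `"neighbor"` or `"mean_of_both"`.
#' @param min_cells Minimum held-out cells per cell type (default 25).
#' @return Tibble: one row per qualifying cell type with `prediction_score`
#'   and `baseline_score`; attribute `p_value`.
#' @export
evaluate_cross_time <- function(model, data, held_out_time,
                                held_out_condition = NULL,
                                query_side = c("previous", "subsequent"),
                                condition_mode = c("same", "opposite"),
                                baseline_mode = c("neighbor", "mean_of_both"),
                                min_cells = 25L) {
  query_side <- match.arg(query_side)
  condition_mode <- match.arg(condition_mode)
  baseline_mode <- match.arg(baseline_mode)
  models <- if (inherits(model, "chronocell_model") ||
                inherits(model, "chronocell_mm_model")) list(model) else model
  rna_branch <- get_branch(models[[1]], "RNA")
  cols <- rna_branch$feature_cols %||% seq_len(ncol(data$counts))

  cells <- data$cells
  is_rna <- cells$modality == "RNA"
  if (all(is.na(cells$cell_type))) abort("Cell-type labels are required for evaluation.")
  times <- sort(unique(cells$time_days[is_rna]))
  if (!held_out_time %in% times) abort("held_out_time not present in the data.")
  others <- setdiff(times, held_out_time)
  prev_t <- if (any(others < held_out_time)) max(others[others < held_out_time]) else NA
  next_t <- if (any(others > held_out_time)) min(others[others > held_out_time]) else NA
  query_time <- if (query_side == "previous") prev_t else next_t
  if (is.na(query_time)) abort(sprintf("No %s time point exists.", query_side))

  truth_sel <- is_rna & cells$time_days == held_out_time
  if (!is.null(held_out_condition)) {
    truth_sel <- truth_sel & cells$condition == held_out_condition
  }
  query_cond_of <- function(truth_cond) {
    if (condition_mode == "same") truth_cond
    else setdiff(c("F", "M"), truth_cond)[1]
  }

  rows <- list()
  for (ct in sort(unique(cells$cell_type[truth_sel]))) {
    if (is.na(ct)) next
    truth_idx <- which(truth_sel & cells$cell_type == ct)
    if (length(truth_idx) < min_cells) next
    truth_cond <- names(which.max(table(cells$condition[truth_idx])))
    qcond <- query_cond_of(truth_cond)
    query_idx <- which(is_rna & cells$time_days == query_time &
                         cells$cell_type == ct & cells$condition == qcond)
    if (length(query_idx) == 0L && condition_mode == "same") {
      # the held-out condition may not be profiled at the query time
      # (alternating-sex designs); fall back to whatever is available
      query_idx <- which(is_rna & cells$time_days == query_time &
                           cells$cell_type == ct)
    }
    if (length(query_idx) == 0L) next
    truth_pb <- pseudobulk_profile(data$counts[truth_idx, cols, drop = FALSE])
    pred <- ensemble_median(models, data = data, cells = query_idx,
                            target_time = held_out_time,
                            target_condition = truth_cond,
                            target_modality = "RNA")
    pred_pb <- colMeans(pred)
    base_pb <- if (baseline_mode == "neighbor") {
      pseudobulk_profile(data$counts[query_idx, cols, drop = FALSE])
    } else {
      sides <- stats::na.omit(c(prev_t, next_t))
      pbs <- lapply(sides, function(tt) {
        i <- which(is_rna & cells$time_days == tt & cells$cell_type == ct)
        if (length(i) == 0L) return(NULL)
        pseudobulk_profile(data$counts[i, cols, drop = FALSE])
      })
      pbs <- pbs[!vapply(pbs, is.null, logical(1))]
      Reduce(`+`, pbs) / length(pbs)
    }
    rows[[length(rows) + 1L]] <- tibble(
      cell_type = ct, held_out_time = held_out_time, query_time = query_time,
      query_side = query_side, condition_mode = condition_mode,
      n_heldout = length(truth_idx), n_query = length(query_idx),
      prediction_score = cor(pred_pb, truth_pb),
      baseline_score = cor(base_pb, truth_pb))
  }
  if (length(rows) == 0L) {
    warn("No cell type passes the held-out cell-count threshold.")
    out <- tibble()
    attr(out, "p_value") <- NA_real_
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chronocell_eval", class(out))
  attr(out, "p_value") <- if (nrow(out) >= 2) {
    suppressWarnings(wilcox.test(out$prediction_score, out$baseline_score,
                                 paired = TRUE, alternative = "greater")$p.value)
  } else NA_real_
  out
}

#' Plot prediction versus baseline pseudobulk correlations
#'
#' @param object Output of [evaluate_cross_time()].
#' @param ... Unused.
#' @return A ggplot scatter with the identity line; points above the line
#'   are cell types where the model beats the baseline.
#' @method autoplot chronocell_eval
#' @export
autoplot.chronocell_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$baseline_score,
                                       y = .data$prediction_score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cell_type)) +
    ggplot2::labs(x = "baseline pseudobulk r", y = "predicted pseudobulk r") +
    ggplot2::theme_minimal()
}
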