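#' Map peaks to genes via strand-aware upstream windows
#'
#' A peak is paired with a gene when its interval overlaps the window
#' extending `window` bases upstream of the gene's TSS: `[TSS - window,
#' TSS)` on the plus strand, `(TSS, TSS + window]` on the minus strand.
#' Coordinates are 0-based half-open.
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Data frame with `gene_id`, `chrom`, `tss`, `strand`
#'   (`"+"`/`"-"`).
#' @param window Upstream window size in bases (default 200000).
#' @return Tibble of (`peak_id`, `gene_id`) pairs.
#' @export
map_peaks_to_genes <- function(peaks, genes, window = 200000L) {
  if (any(is.na(genes$strand))) abort("Every gene needs a strand.")
  peaks <- dplyr::select(as_tibble(peaks), "peak_id", "chrom", "start", "end")
  genes <- dplyr::select(as_tibble(genes), "gene_id", "chrom", "tss", "strand") |>
    dplyr::mutate(
      win_start = ifelse(.data$strand == "+", .data$tss - window, .data$tss + 1),
      win_end = ifelse(.data$strand == "+", .data$tss, .data$tss + window + 1))
  dplyr::inner_join(peaks, genes, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::filter(.data$start < .data$win_end, .data$end > .data$win_start) |>
    dplyr::select("peak_id", "gene_id")
}

#' Time-lagged cross-correlation between two trajectories
#'
#' The accessibility trajectory is shifted along time in `step`-day
#' increments over `shift_range`; at each shift `delta` the Pearson
#' correlation between `expr(t)` and the shifted accessibility
#' `acc(t - delta)` is computed over `t` in `core_window`. With the default
#' grid this yields 101 correlations. A positive best shift means the
#' accessibility pattern precedes (leads) the expression pattern.
#'
#' @param times Common sampling grid (days), evenly spaced by `step` and
#'   covering `core_window` expanded by `shift_range`.
#' @param expr_traj,acc_traj Numeric trajectories on `times`.
#' @param shift_range Length-2 shift range in days (default c(-0.5, 0.5)).
#' @param step Shift step in days (default 0.01).
#' @param core_window Window over which correlations are computed
#'   (default c(8, 8.5)).
#' @return List with `shifts`, `corr` (same length), `best_shift` (argmax
#'   correlation, smallest |shift| on ties) and `max_corr`. Correlations
#'   are `NA` for constant trajectories.
#' @export
tlcc_vector <- function(times, expr_traj, acc_traj,
                        shift_range = c(-0.5, 0.5), step = 0.01,
                        core_window = c(8, 8.5)) {
  stopifnot(length(times) == length(expr_traj),
            length(times) == length(acc_traj))
  dt <- diff(times)
  if (any(abs(dt - step) > 1e-9)) {
    abort("`times` must be evenly spaced at `step`.")
  }
  shifts <- seq(shift_range[1], shift_range[2], by = step)
  core <- which(times >= core_window[1] - 1e-9 & times <= core_window[2] + 1e-9)
  if (length(core) < 3L) abort("`core_window` must contain at least 3 grid points.")
  ks <- as.integer(round(shifts / step))
  if (min(core) + min(ks) < 1L || max(core) + max(ks) > length(times)) {
    abort("`times` must cover `core_window` expanded by `shift_range`.")
  }
  e <- expr_traj[core]
  corr <- vapply(ks, function(k) {
    a <- acc_traj[core - k]
    if (sd(e) == 0 || sd(a) == 0) return(NA_real_)
    cor(e, a)
  }, numeric(1))
  if (all(is.na(corr))) {
    return(list(shifts = shifts, corr = corr,
                best_shift = NA_real_, max_corr = NA_real_))
  }
  mx <- max(corr, na.rm = TRUE)
  cand <- which(!is.na(corr) & abs(corr - mx) < 1e-12)
  best <- cand[which.min(abs(shifts[cand]))]
  list(shifts = shifts, corr = corr,
       best_shift = shifts[best], max_corr = mx)
}

#' TLCC matrix across an ensemble, a query cell and its neighbours
#'
#' For the query cell and each neighbour, expression and accessibility
#' trajectories are predicted over `time_grid` (element-wise ensemble
#' median across `models`), and [tlcc_vector()] is computed for every
#' candidate (peak, gene) pair. Columns (pair x cell) with maximum
#' correlation below `min_corr` are removed, and pairs surviving in at most
#' one cell are dropped.
#'
#' @param models List of trained multimodal models.
#' @param data The [timeseries_dataset()].
#' @param query_cell Query cell id (RNA cell).
#' @param neighbor_cells Cell ids from [aggregate_neighbors()] (may be
#'   empty).
#' @param pairs Tibble of (`peak_id`, `gene_id`) from
#'   [map_peaks_to_genes()].
#' @param time_grid Prediction grid (default `seq(7.5, 9, 0.01)`).
#' @param shift_range,step,core_window Passed to [tlcc_vector()].
#' @param min_corr Column filter on maximum correlation (default 0.5).
#' @param log_expr Correlate log-scale expression trajectories
#'   (default `TRUE`). Expression programs act multiplicatively, so the
#'   log scale keeps a time-shifted program affinely comparable to the
#'   accessibility probability trajectory; on the linear scale the
#'   exponential skew systematically displaces the correlation argmax.
#' @return A `tlcc_matrix`: list with `shifts`, `corr` (shifts x surviving
#'   columns) and `columns` (tibble `peak_id`, `gene_id`, `cell`,
#'   `best_shift`, `max_corr`).
#' @export
tlcc_matrix <- function(models, data, query_cell, neighbor_cells, pairs,
                        time_grid = seq(7.5, 9, by = 0.01),
                        shift_range = c(-0.5, 0.5), step = 0.01,
                        core_window = c(8, 8.5), min_corr = 0.5,
                        log_expr = TRUE) {
  if (inherits(models, "chronocell_mm_model")) models <- list(models)
  cells_used <- c(query_cell, neighbor_cells)
  rna_ids <- get_branch(models[[1]], "RNA")$feature_ids
  atac_ids <- get_branch(models[[1]], "ATAC")$feature_ids
  pairs <- dplyr::filter(as_tibble(pairs),
                         .data$gene_id %in% rna_ids, .data$peak_id %in% atac_ids)
  if (nrow(pairs) == 0L) abort("No candidate pairs lie in the model feature space.")
  cols <- list(); corrs <- list()
  for (cell in cells_used) {
    expr_list <- lapply(models, function(m) {
      predict_trajectory(m, data, cell, time_grid, target_modality = "RNA")
    })
    acc_list <- lapply(models, function(m) {
      predict_trajectory(m, data, cell, time_grid, target_modality = "ATAC")
    })
    med <- function(lst) {
      if (length(lst) == 1L) return(lst[[1]])
      arr <- array(unlist(lst), dim = c(dim(lst[[1]]), length(lst)))
      out <- apply(arr, c(1, 2), median)
      dimnames(out) <- dimnames(lst[[1]])
      out
    }
    expr_traj <- med(expr_list); acc_traj <- med(acc_list)
    if (log_expr) expr_traj <- log(expr_traj + 1e-9)
    for (r in seq_len(nrow(pairs))) {
      tv <- tlcc_vector(time_grid,
                        expr_traj[, pairs$gene_id[r]],
                        acc_traj[, pairs$peak_id[r]],
                        shift_range, step, core_window)
      if (is.na(tv$max_corr) || tv$max_corr < min_corr) next
      cols[[length(cols) + 1L]] <- tibble(
        peak_id = pairs$peak_id[r], gene_id = pairs$gene_id[r], cell = cell,
        best_shift = tv$best_shift, max_corr = tv$max_corr)
      corrs[[length(corrs) + 1L]] <- tv$corr
    }
  }
  if (length(cols) == 0L) {
    warn("No (pair, cell) column passes the correlation filter.")
    return(structure(list(shifts = seq(shift_range[1], shift_range[2], by = step),
                          corr = matrix(numeric(0), nrow = length(seq(shift_range[1], shift_range[2], by = step))),
                          columns = tibble()),
                     class = "tlcc_matrix"))
  }
  columns <- dplyr::bind_rows(cols)
  corr <- do.call(cbind, corrs)
  # keep pairs surviving in more than one cell
  keycount <- columns |>
    dplyr::count(.data$peak_id, .data$gene_id, name = "n_cells")
  columns <- dplyr::left_join(columns, keycount, by = c("peak_id", "gene_id"))
  keep <- columns$n_cells > 1
  if (!any(keep)) warn("No pair survives in more than one cell.")
  structure(list(shifts = seq(shift_range[1], shift_range[2], by = step),
                 corr = corr[, keep, drop = FALSE],
                 columns = columns[keep, , drop = FALSE]),
            class = "tlcc_matrix")
}

#' @export
print.tlcc_matrix <- function(x, ...) {
  cat(sprintf("<tlcc_matrix> %d shifts x %d (pair, cell) columns, %d pairs\n",
              length(x$shifts), ncol(x$corr),
              nrow(unique(x$columns[c("peak_id", "gene_id")]))))
  invisible(x)
}

#' Classify lag direction per peak-gene pair
#'
#' A pair is `"before"` (chromatin accessibility changes ahead of
#' expression) when its best shift is positive in every surviving cell,
#' `"after"` when negative in every cell, `"unclassified"` otherwise.
#'
#' @param x A [tlcc_matrix()].
#' @return Tibble: `peak_id`, `gene_id`, `n_cells`, `median_shift`,
#'   `category`.
#' @export
classify_lag_direction <- function(x) {
  stopifnot(inherits(x, "tlcc_matrix"))
  if (nrow(x$columns) == 0L) return(tibble())
  x$columns |>
    dplyr::group_by(.data$peak_id, .data$gene_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     median_shift = median(.data$best_shift),
                     category = if (all(.data$best_shift > 0)) "before"
                     else if (all(.data$best_shift < 0)) "after"
                     else "unclassified",
                     .groups = "drop")
}

#' @export
tidy.tlcc_matrix <- function(x, ...) classify_lag_direction(x)

#' Heatmap of a TLCC matrix
#'
#' @param object A [tlcc_matrix()].
#' @param ... Unused.
#' @return A ggplot heatmap: shift on the y axis, columns ordered by best
#'   shift.
#' @method autoplot tlcc_matrix
#' @export
autoplot.tlcc_matrix <- function(object, ...) {
  if (ncol(object$corr) == 0L) abort("Empty TLCC matrix.")
  ord <- order(object$columns$best_shift)
  df <- tidyr::expand_grid(col = seq_along(ord), shift = object$shifts)
  df$corr <- as.vector(object$corr[, ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$shift,
                                   fill = .data$corr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "(peak, gene) x cell", y = "shift (day)") +
    ggplot2::theme_minimal()
}
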