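#' Signed-rank score of paired differences
#'
#' The Wilcoxon W+ statistic normalised to `[0, 1]`: absolute differences are
#' ranked (average ranks on ties, zeros dropped) and the sum of ranks of the
#' positive differences is divided by `n(n+1)/2`. Under exchangeable signs
#' the score is 0.5; 1 means every difference is positive and 0 every
#' difference negative.
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @return Score in `[0, 1]`, or `NA` when all differences are zero.
#' @examples
#' signed_rank_score(c(1, -2, 3)) # (1 + 3) / 6
#' @export
signed_rank_score <- function(paired_diffs) {
  d <- paired_diffs[is.finite(paired_diffs) & paired_diffs != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  sum(r[d > 0]) / (n * (n + 1) / 2)
}

#' Depth-normalised pseudobulk profile
#'
#' Each cell is normalised to its total count (so every cell lies on the
#' simplex) before averaging; the result sums to one. Cells with zero depth
#' are excluded with a warning.
#'
#' @param counts Matrix of counts, cells x features (dense or sparse).
#' @return Numeric vector, one value per feature.
#' @export
pseudobulk_profile <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  depth <- Matrix::rowSums(counts)
  if (any(depth == 0)) {
    warn(sprintf("Excluding %d zero-depth cell(s) from the pseudobulk.", sum(depth == 0)))
    counts <- counts[depth > 0, , drop = FALSE]
    depth <- depth[depth > 0]
  }
  if (length(depth) == 0L) abort("No cells with positive depth.")
  as.numeric(Matrix::colSums(counts / depth)) / length(depth)
}

#' Local inverse Simpson index (LISI) of label mixing
#'
#' For each cell, neighbour weights over its `n_neighbors` nearest cells are
#' set by a Gaussian kernel whose bandwidth is tuned (by bisection on the
#' entropy) so the weight distribution has the requested perplexity; the
#' per-cell score is the inverse Simpson index of the weighted label
#' frequencies. Scores lie in `[1, #levels]`; higher means better mixing of
#' labels in the embedding neighbourhood.
#'
#' @param embeddings Numeric matrix, cells x dimensions.
#' @param labels Vector of labels, one per cell.
#' @param perplexity Target perplexity of the kernel (default 30).
#' @param n_neighbors Neighbourhood size cap (default `3 * perplexity`,
#'   at most 90).
#' @return List with `per_cell` (numeric vector) and `mean`.
#' @export
lisi_score <- function(embeddings, labels, perplexity = 30, n_neighbors = NULL) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2L) abort("Need at least 2 cells.")
  labels <- as.character(labels)
  if (perplexity >= n) abort("`perplexity` must be smaller than the number of cells.")
  k <- min(n - 1L, as.integer(n_neighbors %||% min(3 * perplexity, 90)))
  lv <- sort(unique(labels))
  if (length(lv) == 1L) return(list(per_cell = rep(1, n), mean = 1))
  d2 <- as.matrix(dist(embeddings))^2
  per_cell <- vapply(seq_len(n), function(i) {
    ord <- order(d2[i, -i])[seq_len(k)]
    nb <- setdiff(seq_len(n), i)[ord]
    di <- d2[i, nb]
    # bisection on log-precision for the target entropy log(perplexity)
    target <- log(min(perplexity, k))
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      s <- sum(w)
      if (s == 0) { h <- 0 } else {
        p <- w / s
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    if (sum(w) == 0) w <- rep(1, length(di))
    p <- w / sum(w)
    freq <- vapply(lv, function(l) sum(p[labels[nb] == l]), numeric(1))
    1 / sum(freq^2)
  }, numeric(1))
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical), same length.
#' @return AUROC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1].")
  p.adjust(pvalues, method = "BH")
}

#' Enumerate the default hyperparameter grid
#'
#' Latent dimension in \{25, 50, 100\}, minimum time-encoding wavelength in
#' \{1, 2 * pi\}, and (for multimodal training) embedding-alignment weight
#' lambda in \{1, 100, 10000\}: 18 configurations.
#'
#' @param latent_dim,min_wavelength,lambda_mse Grid values.
#' @return Tibble with one row per configuration, in grid order.
#' @export
hyperparameter_grid <- function(latent_dim = c(25L, 50L, 100L),
                                min_wavelength = c(1, 2 * pi),
                                lambda_mse = c(1, 100, 10000)) {
  tidyr::expand_grid(latent_dim = latent_dim,
                     min_wavelength = min_wavelength,
                     lambda_mse = lambda_mse)
}

#' Select the best configuration by summed rank
#'
#' Each criterion column is ranked across configurations (higher is better
#' unless the column name ends in `"loss"`, in which case lower is better);
#' the configuration with the smallest summed rank wins, ties broken by row
#' order.
#'
#' @param grid_results Data frame: one row per configuration; columns naming
#'   configurations plus numeric criterion columns.
#' @param criteria Character vector of criterion column names.
#' @return The winning row (tibble, one row) with a `rank_sum` column.
#' @export
select_model <- function(grid_results, criteria) {
  grid_results <- as_tibble(grid_results)
  missing_cols <- setdiff(criteria, names(grid_results))
  if (length(missing_cols) > 0L) {
    abort(paste0("Criterion column(s) absent: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(vapply(grid_results[criteria], function(x) any(!is.finite(x)), logical(1)))) {
    abort("All configurations must carry finite values for every criterion.")
  }
  ranks <- vapply(criteria, function(cr) {
    x <- grid_results[[cr]]
    if (grepl("loss$", cr)) rank(x, ties.method = "average")
    else rank(-x, ties.method = "average")
  }, numeric(nrow(grid_results)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  rs <- rowSums(ranks)
  best <- which.min(rs)  # which.min takes the first on ties = config order
  out <- grid_results[best, , drop = FALSE]
  out$rank_sum <- rs[best]
  out
}

#' Per-peak agreement between predicted and observed accessibility
#'
#' Peaks accessible in at most `min_accessible_frac` of cells are excluded.
#' For each kept peak the AUROC of the predicted probability against the
#' binary truth is computed across cells, together with a one-sided
#' Wilcoxon rank-sum p-value (predicted accessibility higher in accessible
#' cells); p-values are BH-adjusted across kept peaks.
#'
#' @param predicted_atac Matrix of predicted accessibility probabilities,
#'   cells x peaks.
#' @param true_atac Binary matrix, same shape.
#' @param min_accessible_frac Exclusion threshold (default 0.05).
#' @return Tibble with one row per kept peak: `peak`, `frac_accessible`,
#'   `auroc`, `p`, `q`, `significant`; attribute `frac_significant`.
#' @export
evaluate_peakwise <- function(predicted_atac, true_atac,
                              min_accessible_frac = 0.05) {
  stopifnot(all(dim(predicted_atac) == dim(true_atac)))
  true_atac <- as.matrix(true_atac)
  predicted_atac <- as.matrix(predicted_atac)
  frac <- colMeans(true_atac > 0)
  keep <- which(frac > min_accessible_frac)
  if (length(keep) == 0L) abort("No peaks pass the accessibility filter.")
  peak_ids <- colnames(true_atac) %||% as.character(seq_len(ncol(true_atac)))
  res <- purrr::map_dfr(keep, function(j) {
    y <- true_atac[, j] > 0
    s <- predicted_atac[, j]
    p <- tryCatch(
      wilcox.test(s[y], s[!y], alternative = "greater", exact = FALSE)$p.value,
      error = function(e) NA_real_)
    tibble(peak = peak_ids[j], frac_accessible = frac[j],
           auroc = auroc(s, y), p = p)
  })
  res$q <- bh_fdr(res$p)
  res$significant <- !is.na(res$q) & res$q <= 0.05
  attr(res, "frac_significant") <- mean(res$significant)
  res
}

#' Per-peak direction-of-change score between two predicted states
#'
#' For each peak, the signed-rank score of the per-cell paired differences
#' `t2 - t1`; across an ensemble of models, take the per-peak median of
#' these scores (see [ensemble_median()] for profile-level medians).
#'
#' @param predicted_t1,predicted_t2 Matched matrices, cells x peaks.
#' @return Numeric vector of scores in `[0, 1]` per peak (`NA` where no
#'   nonzero pairs exist).
#' @export
differential_direction_score <- function(predicted_t1, predicted_t2) {
  stopifnot(all(dim(predicted_t1) == dim(predicted_t2)))
  diffs <- as.matrix(predicted_t2) - as.matrix(predicted_t1)
  apply(diffs, 2, signed_rank_score)
}
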