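#' Per-gene, per-cell-type, per-time sex-bias scores
#'
#' For every RNA cell the denoised profile is predicted under both sexes
#' (factor swap at the cell's own time); for each (cell type, time point)
#' the cells from the current, previous and subsequent time points are
#' pooled and each gene scored with the signed-rank score of the per-cell
#' female-minus-male predicted differences. Across an ensemble, the median
#' of the per-model scores is reported. A score of 1 (0) means strongly
#' female- (male-) biased; 0.5 means no sex difference. Scores are reported
#' only when more than `min_cells` cells are pooled.
#'
#' @param models A trained model or list of models (ensemble).
#' @param data A [timeseries_dataset()].
#' @param cell_types Cell types to score (default: all labelled).
#' @param time_points Time points to score (default: all observed).
#' @param min_cells Minimum pooled cells for a score (default 50).
#' @param pool_neighbors Pool current, previous and subsequent time points
#'   (default `TRUE`); at series boundaries whatever exists is pooled.
#' @return A `sexbias_table` tibble: `gene`, `cell_type`, `time_days`,
#'   `score`, `n_cells`, `mean_expr_F`, `mean_expr_M`.
#' @export
compute_sexbias_table <- function(models, data, cell_types = NULL,
                                  time_points = NULL, min_cells = 50L,
                                  pool_neighbors = TRUE) {
  if (inherits(models, "chronocell_model") ||
      inherits(models, "chronocell_mm_model")) models <- list(models)
  br <- get_branch(models[[1]], "RNA")
  if (!all(c("F", "M") %in% br$condition_levels)) {
    abort("The model must know condition levels 'F' and 'M'.")
  }
  cells <- data$cells
  is_rna <- cells$modality == "RNA"
  cell_types <- cell_types %||% sort(unique(cells$cell_type[is_rna & !is.na(cells$cell_type)]))
  time_points <- time_points %||% sort(unique(cells$time_days[is_rna]))
  all_times <- sort(unique(cells$time_days[is_rna]))
  genes <- br$feature_ids

  # target time varies per cell (its own time); handled time point by time point
  score_rows <- list()
  for (tp in time_points) {
    pool_times <- if (pool_neighbors) {
      pos <- match(tp, all_times)
      all_times[stats::na.omit(c(pos - 1, pos, pos + 1))]
    } else tp
    pool_idx <- which(is_rna & cells$time_days %in% pool_times)
    if (length(pool_idx) == 0L) next
    # predictions at each pooled cell's own time, both sexes, per model
    diffs <- vector("list", length(models))
    meanF <- meanM <- vector("list", length(models))
    for (mi in seq_along(models)) {
      pF <- matrix(NA_real_, length(pool_idx), length(genes))
      pM <- matrix(NA_real_, length(pool_idx), length(genes))
      for (tt in unique(cells$time_days[pool_idx])) {
        sel <- which(cells$time_days[pool_idx] == tt)
        pF[sel, ] <- predict_profiles(models[[mi]], data, pool_idx[sel],
                                      target_time = tt, target_condition = "F",
                                      target_modality = "RNA")
        pM[sel, ] <- predict_profiles(models[[mi]], data, pool_idx[sel],
                                      target_time = tt, target_condition = "M",
                                      target_modality = "RNA")
      }
      diffs[[mi]] <- pF - pM
      meanF[[mi]] <- pF; meanM[[mi]] <- pM
    }
    for (ct in cell_types) {
      sel <- which(cells$cell_type[pool_idx] == ct)
      n <- length(sel)
      if (n == 0L) next
      if (n <= min_cells) {
        score <- rep(NA_real_, length(genes))
      } else {
        per_model_scores <- vapply(diffs, function(d) {
          apply(d[sel, , drop = FALSE], 2, signed_rank_score)
        }, numeric(length(genes)))
        score <- apply(matrix(per_model_scores, ncol = length(models)), 1,
                       median, na.rm = TRUE)
      }
      mF <- Reduce(`+`, lapply(meanF, function(p) colMeans(p[sel, , drop = FALSE]))) /
        length(models)
      mM <- Reduce(`+`, lapply(meanM, function(p) colMeans(p[sel, , drop = FALSE]))) /
        length(models)
      score_rows[[length(score_rows) + 1L]] <- tibble(
        gene = genes, cell_type = ct, time_days = tp,
        score = score, n_cells = n, mean_expr_F = mF, mean_expr_M = mM)
    }
  }
  out <- dplyr::bind_rows(score_rows)
  class(out) <- c("sexbias_table", class(out))
  out
}

#' @method autoplot sexbias_table
#' @export
autoplot.sexbias_table <- function(object, cell_type = NULL, ...) {
  df <- object
  if (!is.null(cell_type)) df <- dplyr::filter(df, .data$cell_type == !!cell_type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0.5) +
    ggplot2::facet_wrap(~ .data$cell_type) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "sex-bias score (0 = male-biased, 1 = female-biased)") +
    ggplot2::theme_minimal()
}

#' Genes with a consistent sex bias across time in a cell type
#'
#' Restricted to time points with more than `min_cells` cells and to genes
#' in the top half of predicted mean expression (averaged over sexes) at
#' every qualifying time point; female-biased genes have score > 0.5 at all
#' qualifying time points and male-biased genes score < 0.5 at all.
#'
#' @param table A [compute_sexbias_table()] result.
#' @param cell_type Cell type to examine.
#' @param min_cells Qualification threshold on pooled cells (default 25).
#' @return List with `female_set` and `male_set` (character vectors).
#' @export
consistent_bias_genes <- function(table, cell_type, min_cells = 25L) {
  df <- dplyr::filter(table, .data$cell_type == !!cell_type,
                      .data$n_cells > min_cells, !is.na(.data$score))
  if (nrow(df) == 0L) {
    warn("No qualifying time points; returning empty sets.")
    return(list(female_set = character(0), male_set = character(0)))
  }
  df <- dplyr::mutate(df, mean_expr = (.data$mean_expr_F + .data$mean_expr_M) / 2)
  expressed <- df |>
    dplyr::group_by(.data$time_days) |>
    dplyr::mutate(top_half = .data$mean_expr >= median(.data$mean_expr)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(always_top = all(.data$top_half),
                     all_f = all(.data$score > 0.5),
                     all_m = all(.data$score < 0.5), .groups = "drop")
  list(female_set = expressed$gene[expressed$always_top & expressed$all_f],
       male_set = expressed$gene[expressed$always_top & expressed$all_m])
}

#' One-sided rank-sum test that one gene set scores higher than another
#'
#' Mann-Whitney test of `set_a` scores exceeding `set_b` scores; exact
#' enumeration for small samples (total n <= 12, no ties), normal
#' approximation otherwise.
#'
#' @param scores_by_gene Named numeric vector or two-column data frame
#'   (`gene`, `score`).
#' @param set_a,set_b Character vectors of gene names.
#' @return One-sided p-value.
#' @export
geneset_shift_test <- function(scores_by_gene, set_a, set_b) {
  if (is.data.frame(scores_by_gene)) {
    scores_by_gene <- setNames(scores_by_gene$score, scores_by_gene$gene)
  }
  a <- scores_by_gene[intersect(set_a, names(scores_by_gene))]
  b <- scores_by_gene[intersect(set_b, names(scores_by_gene))]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both gene sets must intersect the scored genes.")
  }
  exact <- (length(a) + length(b)) <= 12 && !anyDuplicated(c(a, b))
  suppressWarnings(
    wilcox.test(a, b, alternative = "greater", exact = exact,
                correct = !exact)$p.value)
}

#' Interaction odds ratio between two gene sets with a permutation null
#'
#' Odds of an interaction between the candidate autosomal set and the
#' X-linked set versus the odds between the remaining autosomal universe
#' and the X-linked set, with the Haldane-Anscombe 0.5 correction when any
#' contingency cell is zero. The null redraws `|candidate|` genes from the
#' autosomal universe `n_perm` times; the p-value is
#' `(1 + #{null OR >= observed}) / (n_perm + 1)`. The test is skipped
#' (returns `NA`) when fewer than `min_edges` interactions touch the
#' relevant pairs.
#'
#' @param graph Two-column data frame or matrix of undirected edges (gene
#'   identifiers).
#' @param female_autosomal Candidate autosomal gene set.
#' @param female_xlinked X-linked gene set.
#' @param autosomal_universe Autosomal universe for the null draws.
#' @param n_perm Number of permutations (default 100).
#' @param seed Seed for the permutation draws.
#' @param min_edges Minimum relevant interactions to run the test
#'   (default 50).
#' @return List with `odds_ratio`, `p_value`, `n_edges`.
#' @export
ppi_odds_ratio_test <- function(graph, female_autosomal, female_xlinked,
                                autosomal_universe, n_perm = 100L, seed = 1L,
                                min_edges = 50L) {
  if (length(autosomal_universe) == 0L) abort("Empty autosomal universe.")
  graph <- as.matrix(graph)[, 1:2, drop = FALSE]
  # undirected: index edges both ways
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_set <- unique(key(graph[, 1], graph[, 2]))
  or_for <- function(cand) {
    other <- setdiff(autosomal_universe, cand)
    n_cand_pairs <- length(cand) * length(female_xlinked)
    n_other_pairs <- length(other) * length(female_xlinked)
    e_cand <- sum(key(rep(cand, each = length(female_xlinked)),
                      rep(female_xlinked, length(cand))) %in% edge_set)
    e_other <- sum(key(rep(other, each = length(female_xlinked)),
                       rep(female_xlinked, length(other))) %in% edge_set)
    cells <- c(a = e_cand, b = n_cand_pairs - e_cand,
               c = e_other, d = n_other_pairs - e_other)
    if (any(cells == 0)) cells <- cells + 0.5
    list(or = (cells["a"] / cells["b"]) / (cells["c"] / cells["d"]),
         edges = e_cand + e_other)
  }
  obs <- or_for(female_autosomal)
  if (obs$edges < min_edges) {
    return(list(odds_ratio = NA_real_, p_value = NA_real_, n_edges = obs$edges))
  }
  null_or <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      or_for(sample(autosomal_universe, length(female_autosomal)))$or
    }, numeric(1))
  })
  list(odds_ratio = unname(obs$or),
       p_value = (1 + sum(null_or >= obs$or)) / (n_perm + 1),
       n_edges = obs$edges)
}

#' Hypergeometric enrichment of a study set in named term sets
#'
#' Upper-tail hypergeometric p per term (probability of at least the
#' observed overlap), BH-adjusted across terms.
#'
#' @param study_set Character vector of genes (subset of `universe`).
#' @param term_sets Named list of character vectors.
#' @param universe Character vector of all genes.
#' @return Tibble: `term`, `overlap`, `term_size`, `p`, `q`, `significant`
#'   (q <= 0.05), ordered as `term_sets`.
#' @export
hypergeometric_enrichment <- function(study_set, term_sets, universe) {
  if (length(universe) == 0L) abort("Empty universe.")
  study_set <- intersect(study_set, universe)
  n_u <- length(universe); n_s <- length(study_set)
  res <- purrr::imap_dfr(term_sets, function(ts, nm) {
    ts <- intersect(ts, universe)
    ov <- length(intersect(ts, study_set))
    p <- phyper(ov - 1, length(ts), n_u - length(ts), n_s, lower.tail = FALSE)
    tibble(term = nm, overlap = ov, term_size = length(ts), p = p)
  })
  res$q <- bh_fdr(res$p)
  res$significant <- res$q <= 0.05
  res
}
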