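#' Single-cell time-series dataset container
#'
#' Bundles a cells-by-features count matrix with per-cell metadata (time in
#' days, condition, batch, modality, optional co-assay pairing and cell-type
#' labels) and optional per-feature genomic coordinates. ATAC rows are
#' binarized on construction; genomic coordinates are 0-based half-open.
#'
#' @param counts Non-negative count matrix, cells x features (dense or
#'   `Matrix` sparse). Row/column names, if absent, are generated.
#' @param cells Data frame with one row per cell. Required columns:
#'   `time_days` (finite numeric) and `modality` (`"RNA"` or `"ATAC"`).
#'   Optional: `cell_id`, `condition`, `batch`, `pair_id`, `cell_type`.
#' @param features Optional data frame with one row per feature; columns
#'   `feature_id` plus optional `chrom`, `start`, `end`, `strand` (`+`/`-`),
#'   `tss`.
#' @return A `timeseries_dataset`: list with elements `counts` (sparse
#'   matrix), `cells` (tibble), `features` (tibble).
#' @export
timeseries_dataset <- function(counts, cells, features = NULL) {
  counts <- as(as(Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  cells <- as_tibble(cells)
  if (nrow(cells) != nrow(counts)) {
    abort(sprintf(
      "Cell axis mismatch: metadata has %d rows but the matrix has %d cells (rows).",
      nrow(cells), nrow(counts)))
  }
  if (!"time_days" %in% names(cells)) {
    abort("`cells` must contain a `time_days` column (or convert somites first).")
  }
  if (any(!is.finite(cells$time_days))) {
    abort("Every cell must have a finite `time_days`; cells with missing time are rejected.")
  }
  if (!"modality" %in% names(cells)) abort("`cells` must contain a `modality` column.")
  bad_mod <- setdiff(unique(as.character(cells$modality)), c("RNA", "ATAC"))
  if (length(bad_mod) > 0L) {
    abort(paste0("Unknown modality tag(s): ", paste(sQuote(bad_mod), collapse = ", "),
                 " (expected 'RNA' or 'ATAC')."))
  }
  if (min(counts) < 0) abort("Counts must be non-negative.")
  if (!"cell_id" %in% names(cells)) {
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
  }
  for (col in c("condition", "batch", "pair_id", "cell_type")) {
    if (!col %in% names(cells)) {
      cells[[col]] <- if (col %in% c("condition", "batch")) {
        rep(if (col == "condition") "unknown" else "batch1", nrow(cells))
      } else rep(NA_character_, nrow(cells))
    }
    cells[[col]] <- as.character(cells[[col]])
  }
  if (is.null(features)) {
    features <- tibble(feature_id = sprintf("feat%05d", seq_len(ncol(counts))))
  }
  features <- as_tibble(features)
  if (nrow(features) != ncol(counts)) {
    abort(sprintf(
      "Feature axis mismatch: feature table has %d rows but the matrix has %d features (columns).",
      nrow(features), ncol(counts)))
  }
  # binarize ATAC profiles before any modeling
  atac <- which(cells$modality == "ATAC")
  if (length(atac) > 0L) {
    sub <- counts[atac, , drop = FALSE]
    sub@x <- as.numeric(sub@x > 0)
    counts[atac, ] <- sub
  }
  rownames(counts) <- cells$cell_id
  colnames(counts) <- features$feature_id
  pid <- cells$pair_id[!is.na(cells$pair_id)]
  if (length(pid) > 0L) {
    per_pair <- table(cells$pair_id, cells$modality)
    if (any(per_pair > 1L) ||
        any(rowSums(per_pair > 0) == 2 & (per_pair[, 1] != 1 | per_pair[, 2] != 1))) {
      abort("Each `pair_id` must link exactly one RNA cell to one ATAC cell.")
    }
  }
  structure(list(counts = counts, cells = cells, features = features),
            class = "timeseries_dataset")
}

#' @export
print.timeseries_dataset <- function(x, ...) {
  cat(sprintf("<timeseries_dataset> %d cells x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  modalities:", paste(names(table(x$cells$modality)), table(x$cells$modality),
                             sep = "=", collapse = ", "), "\n")
  cat("  time points:", paste(sort(unique(x$cells$time_days)), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$cells$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.timeseries_dataset <- function(x) dim(x$counts)

#' Subset a time-series dataset by cell index
#'
#' @param data A [timeseries_dataset()].
#' @param i Integer or logical index over cells.
#' @return A `timeseries_dataset` restricted to the selected cells.
#' @export
subset_cells <- function(data, i) {
  stopifnot(inherits(data, "timeseries_dataset"))
  out <- data
  out$counts <- data$counts[i, , drop = FALSE]
  out$cells <- data$cells[i, , drop = FALSE]
  out
}

#' Read a dataset from MatrixMarket + delimited metadata
#'
#' Expects a coordinate MTX file oriented cells x features, a tab-delimited
#' metadata table with one row per cell (columns `time_days` or `somite`,
#' `modality`, and optionally `condition`, `batch`, `pair_id`, `cell_type`),
#' and optionally a feature table. When the metadata carries `somite` instead
#' of `time_days`, supply `anchor_somite`/`anchor_day` to convert.
#'
#' @param counts_path Path to the MTX file.
#' @param metadata_path Path to the tab-delimited per-cell metadata.
#' @param features_path Optional path to a tab-delimited feature table.
#' @param anchor_somite,anchor_day Somite-staging anchor used only when the
#'   metadata has a `somite` column; see [somite_to_time()].
#' @return A [timeseries_dataset()].
#' @export
load_dataset <- function(counts_path, metadata_path, features_path = NULL,
                         anchor_somite = NULL, anchor_day = NULL) {
  for (p in c(counts_path, metadata_path, features_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("File not found: ", p))
  }
  counts <- readMM(counts_path)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  if (!"time_days" %in% names(meta)) {
    if ("somite" %in% names(meta)) {
      if (is.null(anchor_somite) || is.null(anchor_day)) {
        abort("Metadata has `somite`; supply `anchor_somite` and `anchor_day` to convert.")
      }
      meta$time_days <- somite_to_time(meta$somite, anchor_somite, anchor_day)
    } else {
      abort("Metadata must contain `time_days` or `somite`.")
    }
  }
  features <- if (!is.null(features_path)) {
    readr::read_tsv(features_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  timeseries_dataset(counts, meta, features)
}

#' Write a dataset as MTX + delimited metadata
#'
#' Inverse of [load_dataset()]: a round trip reproduces counts and metadata.
#'
#' @param data A [timeseries_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`counts`, `metadata`, `features`).
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "timeseries_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(counts = file.path(dir, "counts.mtx"),
                metadata = file.path(dir, "cells.tsv"),
                features = file.path(dir, "features.tsv"))
  writeMM(data$counts, paths$counts)
  readr::write_tsv(data$cells, paths$metadata, progress = FALSE)
  readr::write_tsv(data$features, paths$features, progress = FALSE)
  invisible(paths)
}

#' Convert a somite count to developmental time in days
#'
#' Early embryos are staged by somite number; stages are mapped to days by
#' assuming equal spacing of 2/34 day per somite around a user-supplied
#' anchor (the somite count whose day is known).
#'
#' @param somite_count Integer vector of somite counts (>= 0).
#' @param anchor_somite Somite count at the anchor stage.
#' @param anchor_day Day corresponding to `anchor_somite`.
#' @return `anchor_day + (somite_count - anchor_somite) * 2/34`, in days.
#' @examples
#' somite_to_time(17, anchor_somite = 0, anchor_day = 8) # 9
#' @export
somite_to_time <- function(somite_count, anchor_somite, anchor_day) {
  if (any(somite_count < 0)) abort("`somite_count` must be >= 0.")
  anchor_day + (somite_count - anchor_somite) * (2 / 34)
}

#' Specification of a train/validation/test split
#'
#' @param held_out_time Time point (day) whose cells form the test set, or
#'   `NULL`.
#' @param held_out_condition Condition level additionally restricting the
#'   test set, or `NULL`.
#' @param val_fraction Fraction of remaining cells per time point assigned to
#'   validation (default 1/5, i.e. a 1:4 validation:training ratio).
#' @param val_cap_per_time Maximum validation cells per time point
#'   (default 2000).
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(held_out_time = NULL, held_out_condition = NULL,
                       val_fraction = 1 / 5, val_cap_per_time = 2000L,
                       seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1) abort("`val_fraction` must be in (0, 1).")
  if (val_cap_per_time < 1) abort("`val_cap_per_time` must be >= 1.")
  structure(list(held_out_time = held_out_time,
                 held_out_condition = held_out_condition,
                 val_fraction = val_fraction,
                 val_cap_per_time = as.integer(val_cap_per_time),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split cells into training, validation and test sets
#'
#' Cells at the held-out time point (and condition, if given) form the test
#' set. The remaining cells are split per time point into validation and
#' training at the `val_fraction` ratio, with the validation size capped at
#' `val_cap_per_time` so abundant time points cannot dominate validation.
#' The split is deterministic given `spec$seed`; changing the seed never
#' changes the test set.
#'
#' @param data A [timeseries_dataset()].
#' @param spec A [split_spec()].
#' @return List with integer cell indices `train`, `val`, `test`: disjoint,
#'   jointly covering all cells.
#' @export
make_splits <- function(data, spec = split_spec()) {
  stopifnot(inherits(data, "timeseries_dataset"), inherits(spec, "split_spec"))
  n <- nrow(data$counts)
  idx <- seq_len(n)
  in_test <- rep(FALSE, n)
  if (!is.null(spec$held_out_time)) {
    hit <- data$cells$time_days == spec$held_out_time
    if (!any(hit)) {
      abort(sprintf("held_out_time = %s matches no cells.", format(spec$held_out_time)))
    }
    if (all(hit)) abort("held_out_time would leave no cells for training.")
    in_test <- hit
  }
  if (!is.null(spec$held_out_condition)) {
    cond_hit <- data$cells$condition == spec$held_out_condition
    in_test <- if (is.null(spec$held_out_time)) cond_hit else in_test & cond_hit
  }
  rest <- idx[!in_test]
  val <- integer(0)
  with_seed(spec$seed, {
    for (tp in sort(unique(data$cells$time_days[rest]))) {
      pool <- rest[data$cells$time_days[rest] == tp]
      n_val <- min(round(length(pool) * spec$val_fraction), spec$val_cap_per_time)
      if (n_val >= 1) val <- c(val, sort(sample(pool, n_val)))
    }
  })
  list(train = setdiff(rest, val), val = sort(val), test = idx[in_test])
}
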