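#' Specification of a synthetic multi-omic time series
#'
#' Describes a seeded simulation of ZINB scRNA-seq counts and binarized
#' scATAC-seq peaks over multiple time points, with cell-type structure,
#' smooth per-gene temporal programs, planted sex effects of known sign,
#' batch effects, co-assay pairing and planted peak-gene time lags. The
#' defaults are the tiny study conditions used throughout the package's
#' tests; see [default_acceptance_spec()].
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type_per_time RNA cells per (cell type, time point, sex).
#' @param atac_cells_per_type_per_time ATAC cells per (cell type, time
#'   point); sexes alternate as for RNA.
#' @param genes,peaks Feature counts.
#' @param time_points Numeric vector of time points (days).
#' @param sex_mask Logical matrix, time points x c("F", "M"): which sexes are
#'   profiled at each time point. Default: sexes alternate with every third
#'   time point doubly profiled, echoing designs where only one sex is
#'   available at most time points.
#' @param n_batches Number of batches; `batch_sd` is the SD of per-batch
#'   gene-level log-scale factors.
#' @param batch_sd Batch effect size on the log scale (default 0.1).
#' @param frac_temporal Fraction of genes carrying a non-constant temporal
#'   program (default 0.6).
#' @param program_amplitude Maximum |amplitude| of temporal programs on the
#'   log scale (default 2).
#' @param n_sex_genes Autosomal sex-biased genes (half female-, half
#'   male-biased).
#' @param sex_logfc Planted |log fold change| (natural log) of sex-biased
#'   genes (default 1).
#' @param n_escape_genes X-linked genes planted female-biased at every time
#'   point, emulating XCI escape (default 8).
#' @param n_lag_pairs Peak-gene pairs with a planted accessibility lead/lag.
#' @param lag_range Range of |tau| in days (default c(0.1, 0.2)); the sign
#'   of each pair's tau is random. Positive tau means accessibility changes
#'   ahead of expression.
#' @param atac_coupling Probability-scale amplitude of planted peak
#'   coupling: a coupled peak's accessibility probability is
#'   `0.5 + sign * atac_coupling * f(t + tau) / |A|`, an affine rescale of
#'   the lagged gene program (default 0.35). The affine (rather than
#'   sigmoidal) coupling keeps the lag identifiable by correlation: the
#'   shifted curves coincide exactly at the true lag.
#' @param theta_meanlog,theta_sdlog Log-normal parameters of per-gene ZINB
#'   inverse dispersion (defaults log(2), 0.5).
#' @param pi_max Per-gene zero-inflation probabilities drawn uniformly from
#'   `[0, pi_max]` (default 0.15).
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters
#'   (defaults log(2000), 0.3).
#' @param coassay_fraction Fraction of ATAC cells that are co-assayed (carry
#'   an RNA twin with a shared `pair_id`; default 0.5).
#' @param seed Integer seed; the simulation is bit-reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cell_types = 3L,
                            cells_per_type_per_time = 60L,
                            atac_cells_per_type_per_time = 30L,
                            genes = 200L, peaks = 300L,
                            time_points = seq(7.5, 9, length.out = 5),
                            sex_mask = NULL,
                            n_batches = 2L, batch_sd = 0.1,
                            frac_temporal = 0.6,
                            program_amplitude = 2,
                            n_sex_genes = 20L, sex_logfc = 1,
                            n_escape_genes = 8L,
                            n_lag_pairs = 50L, lag_range = c(0.1, 0.2),
                            atac_coupling = 0.35,
                            theta_meanlog = log(2), theta_sdlog = 0.5,
                            pi_max = 0.15,
                            depth_meanlog = log(2000), depth_sdlog = 0.3,
                            coassay_fraction = 0.5,
                            seed = 1L) {
  if (is.null(sex_mask)) {
    tps <- length(time_points)
    sex_mask <- cbind(F = rep(c(TRUE, FALSE), length.out = tps),
                      M = rep(c(FALSE, TRUE), length.out = tps))
    both <- seq(3, tps, by = 3)
    sex_mask[both, ] <- TRUE
  }
  if (any(rowSums(sex_mask) == 0)) abort("Every time point needs at least one sex.")
  spec <- list(n_cell_types = as.integer(n_cell_types),
               cells_per_type_per_time = as.integer(cells_per_type_per_time),
               atac_cells_per_type_per_time = as.integer(atac_cells_per_type_per_time),
               genes = as.integer(genes), peaks = as.integer(peaks),
               time_points = time_points, sex_mask = sex_mask,
               n_batches = as.integer(n_batches), batch_sd = batch_sd,
               frac_temporal = frac_temporal,
               program_amplitude = program_amplitude,
               n_sex_genes = as.integer(n_sex_genes), sex_logfc = sex_logfc,
               n_escape_genes = as.integer(n_escape_genes),
               n_lag_pairs = as.integer(n_lag_pairs), lag_range = lag_range,
               atac_coupling = atac_coupling,
               theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
               pi_max = pi_max,
               depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
               coassay_fraction = coassay_fraction,
               seed = as.integer(seed))
  structure(spec, class = "simulation_spec")
}

#' Study-condition presets for the package's validation experiments
#'
#' `tiny` (3 cell types x 5 time points x 200 genes x 300 peaks, about 2000
#' cells) trains in minutes on one CPU and is the scale used by the test
#' suite and acceptance script; `desk` (5 x 8 x 500 x 1000, about 10000
#' cells) exercises the same planted effects at a larger scale. The two
#' share every planted-effect definition and differ only in size.
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param seed Simulation seed.
#' @return A [simulation_spec()].
#' @export
default_acceptance_spec <- function(scale = c("tiny", "desk"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    simulation_spec(seed = seed)
  } else {
    simulation_spec(n_cell_types = 5L, cells_per_type_per_time = 120L,
                    atac_cells_per_type_per_time = 60L,
                    genes = 500L, peaks = 1000L,
                    time_points = seq(7.5, 9.25, by = 0.25),
                    n_sex_genes = 50L, n_escape_genes = 8L,
                    n_lag_pairs = 150L, seed = seed)
  }
}

#' Evaluate a planted temporal program
#'
#' @param family One of `"constant"`, `"linear"`, `"logistic"`,
#'   `"sinusoid"`.
#' @param amplitude Signed amplitude on the log scale.
#' @param center Program center (day).
#' @param period Sinusoid period / linear half-range (day).
#' @param t Times (days).
#' @return Program value(s) on the log-expression scale.
#' @export
temporal_program_value <- function(family, amplitude, center, period, t) {
  switch(family,
         constant = rep(0, length(t)),
         linear = amplitude * (t - center) / (period / 2),
         logistic = amplitude * (2 * stats::plogis((t - center) / 0.2) - 1),
         sinusoid = amplitude * sin(2 * pi * (t - center) / period),
         abort(paste0("Unknown program family: ", family)))
}

# program values for a gene ground-truth table: matrix length(t) x genes
gene_program_matrix <- function(gt_genes, t) {
  out <- vapply(seq_len(nrow(gt_genes)), function(g) {
    temporal_program_value(gt_genes$family[g], gt_genes$amplitude[g],
                           gt_genes$center[g], gt_genes$period[g], t)
  }, numeric(length(t)))
  matrix(out, nrow = length(t))
}

#' Simulate a multi-omic single-cell time series with planted truth
#'
#' RNA counts follow a ZINB with mean `depth * softmax(log-intensity)`,
#' where the per-gene log-intensity is the sum of a cell-type base, a smooth
#' temporal program, a sex effect of known sign and a batch effect. ATAC
#' peaks are Bernoulli with a logit following the coupled gene's program
#' evaluated at `t + tau` for planted pairs. A fraction of ATAC cells carry
#' co-assay `pair_id` links to RNA twins generated from the same underlying
#' cell. Fully deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `data` (a [timeseries_dataset()] holding both
#'   modalities; gene columns first, then peaks, tagged via
#'   `data$features$modality`) and `truth` (list of tibbles `genes`,
#'   `pairs`, `cell_types`).
#' @export
simulate_multiomic_timeseries <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    G <- spec$genes; P <- spec$peaks
    tps <- spec$time_points
    t_center <- mean(range(tps))
    t_span <- diff(range(tps))

    ## ---- gene-level truth ----
    chroms <- c(paste0("chr", 1:5), "chrX")
    gene_chrom <- rep(chroms, length.out = G)
    # escape genes live on chrX; autosomal sex genes off chrX
    x_genes <- which(gene_chrom == "chrX")
    if (length(x_genes) < spec$n_escape_genes + 5) {
      abort("Too few chrX genes; increase `genes`.")
    }
    escape <- sort(sample(x_genes, spec$n_escape_genes))
    auto_pool <- setdiff(seq_len(G), x_genes)
    sex_genes <- sort(sample(auto_pool, spec$n_sex_genes))
    sex_logfc <- rep(0, G)
    sex_logfc[escape] <- spec$sex_logfc
    half <- length(sex_genes) %/% 2
    sex_logfc[sex_genes[seq_len(half)]] <- spec$sex_logfc
    sex_logfc[sex_genes[(half + 1):length(sex_genes)]] <- -spec$sex_logfc

    fam_pool <- c("linear", "logistic", "sinusoid")
    family <- ifelse(runif(G) < spec$frac_temporal,
                     sample(fam_pool, G, replace = TRUE), "constant")
    amplitude <- ifelse(family == "constant", 0,
                        sample(c(-1, 1), G, TRUE) *
                          runif(G, 0.5 * spec$program_amplitude,
                                spec$program_amplitude))
    center <- runif(G, t_center - t_span / 4, t_center + t_span / 4)
    period <- runif(G, t_span, 2 * t_span)
    theta <- rlnorm(G, spec$theta_meanlog, spec$theta_sdlog)
    pi_g <- runif(G, 0, spec$pi_max)
    tss <- integer(G)
    for (ch in chroms) {
      i <- which(gene_chrom == ch)
      tss[i] <- seq_along(i) * 1000000L + 500000L
    }
    gt_genes <- tibble(
      gene_id = sprintf("gene%04d", seq_len(G)),
      chrom = gene_chrom, tss = tss, strand = "+",
      family = family, amplitude = amplitude, center = center,
      period = period, theta = theta, pi = pi_g,
      sex_logfc = sex_logfc, is_escape = seq_len(G) %in% escape,
      is_sex_biased = sex_logfc != 0)
    gt_genes$trend <- as.numeric(gene_program_matrix(gt_genes, max(tps))) -
      as.numeric(gene_program_matrix(gt_genes, min(tps)))

    ## ---- cell types and batches ----
    K <- spec$n_cell_types
    base <- matrix(rnorm(K * G, 0, 1), K, G)
    markers_per_type <- max(5L, G %/% (4L * K))
    for (k in seq_len(K)) {
      base[k, sample(G, markers_per_type)] <- base[k, sample(G, markers_per_type)] + 2
    }
    batch_eff <- matrix(rnorm(spec$n_batches * G, 0, spec$batch_sd),
                        spec$n_batches, G)

    ## ---- peak-level truth ----
    # planted pairs target logistic-program genes: a smooth activation step
    # centred inside the analysis window makes the lag identifiable by
    # correlation (flat tails avoid interpolation edge artifacts), and
    # mirrors chromatin priming around lineage emergence
    dynamic <- which(family == "logistic")
    pair_gene <- sample(dynamic, spec$n_lag_pairs,
                        replace = spec$n_lag_pairs > length(dynamic))
    tau <- sample(c(-1, 1), spec$n_lag_pairs, TRUE) *
      runif(spec$n_lag_pairs, spec$lag_range[1], spec$lag_range[2])
    coupling <- sample(c(-1, 1), spec$n_lag_pairs, TRUE) * spec$atac_coupling
    peak_chrom <- character(P); peak_start <- integer(P)
    peak_gene <- rep(NA_integer_, P)
    peak_tau <- rep(NA_real_, P); peak_coupling <- rep(NA_real_, P)
    for (j in seq_len(spec$n_lag_pairs)) {
      g <- pair_gene[j]
      peak_chrom[j] <- gene_chrom[g]
      peak_start[j] <- tss[g] - as.integer(runif(1, 2e4, 1.9e5))
      peak_gene[j] <- g
      peak_tau[j] <- tau[j]
      peak_coupling[j] <- coupling[j]
    }
    if (P > spec$n_lag_pairs) {
      rest <- (spec$n_lag_pairs + 1):P
      g_rest <- sample(G, length(rest), replace = TRUE)
      peak_chrom[rest] <- gene_chrom[g_rest]
      # placed downstream of the TSS: proximal but outside the upstream window
      peak_start[rest] <- tss[g_rest] + as.integer(runif(length(rest), 2e4, 1.5e5))
    }
    peak_base <- stats::qlogis(runif(P, 0.08, 0.35))
    # cell-type marker peaks so ATAC carries cell-identity signal
    peak_type_eff <- matrix(0, spec$n_cell_types, P)
    for (k in seq_len(spec$n_cell_types)) {
      peak_type_eff[k, sample(P, max(5L, P %/% (4L * spec$n_cell_types)))] <- 2
    }
    gt_pairs <- tibble(
      peak_id = sprintf("peak%04d", seq_len(spec$n_lag_pairs)),
      gene_id = gt_genes$gene_id[pair_gene],
      tau = tau, coupling = coupling)
    features <- dplyr::bind_rows(
      tibble(feature_id = gt_genes$gene_id, modality = "RNA",
             chrom = gt_genes$chrom, start = gt_genes$tss,
             end = gt_genes$tss + 1L, strand = "+", tss = gt_genes$tss),
      tibble(feature_id = sprintf("peak%04d", seq_len(P)), modality = "ATAC",
             chrom = peak_chrom, start = peak_start,
             end = peak_start + 500L, strand = NA_character_,
             tss = NA_integer_))

    ## ---- cells ----
    sexes <- colnames(spec$sex_mask)
    cell_rows <- list(); count_blocks <- list(); rowptr <- 0L
    add_cells <- function(n, type, time, sex, batch, modality, pair_ids) {
      tibble(cell_type = sprintf("type%d", type), time_days = time,
             condition = sex, batch = sprintf("batch%d", batch),
             modality = modality, pair_id = pair_ids)
    }
    rna_logits <- function(type, time, sex, batch) {
      prog <- gene_program_matrix(gt_genes, time)[1, ]
      base[type, ] + prog + sex_logfc * (sex == "F") + batch_eff[batch, ]
    }
    draw_rna <- function(n, lg) {
      rho <- exp(lg - max(lg)); rho <- rho / sum(rho)
      depth <- rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)
      mu <- outer(depth, rho)
      cnt <- matrix(rnbinom(n * G, size = rep(theta, each = n), mu = mu), n, G)
      drop <- matrix(rbinom(n * G, 1, rep(pi_g, each = n)), n, G)
      cnt * (1 - drop)
    }
    # accessibility probability per peak at a time: uncoupled peaks follow a
    # static logit (base + cell-type marker effect); coupled peaks follow an
    # affine rescale of the lagged gene program on the probability scale
    peak_prob <- function(type, time) {
      pq <- stats::plogis(peak_base + peak_type_eff[type, ])
      coupled <- which(!is.na(peak_gene))
      if (length(coupled) > 0) {
        pg <- peak_gene[coupled]
        progs <- vapply(seq_along(coupled), function(i) {
          temporal_program_value(gt_genes$family[pg[i]], gt_genes$amplitude[pg[i]],
                                 gt_genes$center[pg[i]], gt_genes$period[pg[i]],
                                 time + peak_tau[coupled[i]])
        }, numeric(1))
        pq[coupled] <- 0.5 + peak_coupling[coupled] * progs / abs(amplitude[pg])
      }
      pmin(pmax(pq, 0.02), 0.98)
    }
    draw_atac <- function(n, type, time, batch) {
      pq <- peak_prob(type, time)
      matrix(rbinom(n * P, 1, rep(pq, each = n)), n, P, byrow = FALSE)
    }

    pair_counter <- 0L
    for (ti in seq_along(tps)) {
      time <- tps[ti]
      for (k in seq_len(K)) {
        for (s in sexes[spec$sex_mask[ti, ]]) {
          n <- spec$cells_per_type_per_time
          batches <- sample(spec$n_batches, n, replace = TRUE)
          for (b in sort(unique(batches))) {
            nb <- sum(batches == b)
            lg <- rna_logits(k, time, s, b)
            cnt <- draw_rna(nb, lg)
            cell_rows[[length(cell_rows) + 1L]] <-
              add_cells(nb, k, time, s, b, "RNA", rep(NA_character_, nb))
            count_blocks[[length(count_blocks) + 1L]] <-
              cbind(cnt, matrix(0, nb, P))
          }
        }
        # ATAC cells (+ co-assay RNA twins), sex alternating over the mask
        n_at <- spec$atac_cells_per_type_per_time
        if (n_at > 0) {
          s_at <- sexes[spec$sex_mask[ti, ]][1]
          b_at <- sample(spec$n_batches, n_at, replace = TRUE)
          atac_cnt <- draw_atac(n_at, k, time, b_at)
          n_pair <- round(n_at * spec$coassay_fraction)
          pids <- rep(NA_character_, n_at)
          if (n_pair > 0) {
            pids[seq_len(n_pair)] <- sprintf("pair%06d", pair_counter + seq_len(n_pair))
            pair_counter <- pair_counter + n_pair
          }
          cell_rows[[length(cell_rows) + 1L]] <-
            add_cells(n_at, k, time, s_at, 1L, "ATAC", pids)
          count_blocks[[length(count_blocks) + 1L]] <-
            cbind(matrix(0, n_at, G), atac_cnt)
          if (n_pair > 0) {
            lg <- rna_logits(k, time, s_at, 1L)
            cnt <- draw_rna(n_pair, lg)
            cell_rows[[length(cell_rows) + 1L]] <-
              add_cells(n_pair, k, time, s_at, 1L, "RNA", pids[seq_len(n_pair)])
            count_blocks[[length(count_blocks) + 1L]] <-
              cbind(cnt, matrix(0, n_pair, P))
          }
        }
      }
    }
    cells <- dplyr::bind_rows(cell_rows)
    counts <- do.call(rbind, count_blocks)
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
    data <- timeseries_dataset(counts, cells, features)
    truth <- list(genes = gt_genes, pairs = gt_pairs,
                  cell_types = tibble(cell_type = sprintf("type%d", seq_len(K))))
    list(data = data, truth = truth)
  })
}
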