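# Multimodal extension: a Bernoulli-likelihood ATAC branch trained against
# the scRNA-seq reference with a shared time-relevant decoder sub-layer,
# co-assay embedding alignment and cross-modality translation losses.

# backward for the ATAC (Bernoulli) reconstruction + KL objective
atac_backward <- function(params, fw, kl_weight, d_mean_extra = NULL) {
  b <- nrow(fw$x)
  L <- ncol(fw$enc$mean)
  d_plogit <- (fw$dec$p - fw$x) / b
  top <- fw$dec$h[[length(fw$dec$h)]]
  bs <- linear_backward(params$dec$scale, top, d_plogit)
  bt <- trunk_backward(params$dec$trunk, fw$dec$h, bs$dX)
  dz <- bt$dX[, seq_len(L), drop = FALSE]
  d_th <- bt$dX[, L + seq_len(ncol(fw$dec$t_h)), drop = FALSE]
  d_at <- d_th * (fw$dec$t_h > 0)
  btime <- linear_backward(params$dec$time, fw$te, d_at)
  d_mean <- (kl_weight / b) * fw$enc$mean + dz
  d_logvar <- (kl_weight / b) * 0.5 * (exp(fw$enc$logvar) - 1)
  if (!is.null(fw$eps)) {
    d_logvar <- d_logvar + dz * fw$eps * 0.5 * exp(0.5 * fw$enc$logvar)
  }
  if (!is.null(d_mean_extra)) d_mean <- d_mean + d_mean_extra
  htop <- fw$enc$h[[length(fw$enc$h)]]
  bm <- linear_backward(params$enc$mean, htop, d_mean)
  bv <- linear_backward(params$enc$logvar, htop, d_logvar)
  be <- trunk_backward(params$enc$trunk, fw$enc$h, bm$dX + bv$dX)
  list(enc = list(trunk = be$grads, mean = bm$grad, logvar = bv$grad),
       dec = list(time = btime$grad, trunk = bt$grads, scale = bs$grad))
}

atac_forward <- function(params, x, te, cond, batch, eps = NULL) {
  enc <- branch_encode(params, x, te, cond, batch)
  z <- if (is.null(eps)) enc$mean else enc$mean + exp(0.5 * enc$logvar) * eps
  dec <- branch_decode(params, z, te, cond, batch, "bernoulli")
  ll <- bernoulli_loglik(x, dec$p)
  list(enc = enc, dec = dec, z = z, eps = eps, x = x,
       te = te, cond = cond, batch = batch,
       recon = rowSums(ll), kl = kl_gaussian(enc$mean, exp(0.5 * enc$logvar)))
}

mm_zero_time_grad <- function(gr) {
  gr$dec$time <- tree_map(function(x) x * 0, gr$dec$time)
  gr
}

#' Multimodal loss components on given cells
#'
#' Computes, deterministically (posterior means, no sampling):
#' `loss_atac` (negative Bernoulli log-likelihood + KL, mean per ATAC cell),
#' `loss_align` (mean squared difference between paired RNA/ATAC embedding
#' means), `loss_trans_ab` (negative Bernoulli log-likelihood of the true
#' ATAC profile decoded from the paired RNA embedding, mean per pair),
#' `loss_trans_ba` (negative ZINB log-likelihood of the true RNA profile
#' decoded from the paired ATAC embedding), and
#' `loss_multi = loss_atac + lambda * loss_align + loss_trans_ab +
#' loss_trans_ba`.
#'
#' @param model A `chronocell_mm_model` from [train_multimodal()].
#' @param data The [timeseries_dataset()].
#' @param atac_idx Indices of ATAC cells for the reconstruction term.
#' @param pair_idx Optional two-column matrix/data frame of (rna, atac) cell
#'   indices for the alignment/translation terms; defaults to all pairs in
#'   `data`. With no pairs the alignment/translation terms are 0 (warning).
#' @return Named list of the five losses.
#' @export
multimodal_losses <- function(model, data, atac_idx, pair_idx = NULL) {
  stopifnot(inherits(model, "chronocell_mm_model"))
  if (is.null(pair_idx)) pair_idx <- coassay_pairs(data)
  pair_idx <- as.matrix(pair_idx)
  xa <- as.matrix(data$counts[atac_idx, model$atac$feature_cols, drop = FALSE])
  cva <- model_covariates(model$atac, data$cells$time_days[atac_idx],
                          data$cells$condition[atac_idx], data$cells$batch[atac_idx])
  fwa <- atac_forward(model$atac$params, xa, cva$te, cva$cond, cva$batch)
  loss_atac <- mean(-fwa$recon + model$atac$config$kl_weight * fwa$kl)
  if (nrow(pair_idx) == 0L) {
    warn("No co-assay pairs: alignment and translation terms set to 0.")
    return(list(loss_atac = loss_atac, loss_align = 0,
                loss_trans_ab = 0, loss_trans_ba = 0,
                loss_multi = loss_atac))
  }
  pr <- pair_forward(model, data, pair_idx)
  loss_multi <- loss_atac + model$lambda_mse * pr$loss_align +
    pr$loss_trans_ab + pr$loss_trans_ba
  list(loss_atac = loss_atac, loss_align = pr$loss_align,
       loss_trans_ab = pr$loss_trans_ab, loss_trans_ba = pr$loss_trans_ba,
       loss_multi = loss_multi)
}

# embeddings + translation losses for a set of co-assay pairs (means only)
pair_forward <- function(model, data, pair_idx) {
  r_idx <- pair_idx[, 1]; a_idx <- pair_idx[, 2]
  xr <- as.matrix(data$counts[r_idx, model$rna$feature_cols, drop = FALSE])
  xa <- as.matrix(data$counts[a_idx, model$atac$feature_cols, drop = FALSE])
  cvr <- model_covariates(model$rna, data$cells$time_days[r_idx],
                          data$cells$condition[r_idx], data$cells$batch[r_idx])
  cva <- model_covariates(model$atac, data$cells$time_days[a_idx],
                          data$cells$condition[a_idx], data$cells$batch[a_idx])
  enc_r <- branch_encode(model$rna$params, log1p(xr), cvr$te, cvr$cond, cvr$batch)
  enc_a <- branch_encode(model$atac$params, xa, cva$te, cva$cond, cva$batch)
  loss_align <- mean((enc_a$mean - enc_r$mean)^2)
  # ATAC decoded from the RNA embedding
  dec_ab <- branch_decode(model$atac$params, enc_r$mean, cva$te, cva$cond,
                          cva$batch, "bernoulli")
  loss_trans_ab <- mean(-rowSums(bernoulli_loglik(xa, dec_ab$p)))
  # RNA decoded from the ATAC embedding
  lib <- pmax(rowSums(xr), 1)
  dec_ba <- branch_decode(model$rna$params, enc_a$mean, cvr$te, cvr$cond,
                          cvr$batch, "zinb", lib = lib)
  theta <- exp(model$rna$params$log_theta)
  loss_trans_ba <- mean(-rowSums(zinb_loglik(xr, dec_ba$mu, theta, dec_ba$pi)))
  list(enc_r = enc_r, enc_a = enc_a, dec_ab = dec_ab, dec_ba = dec_ba,
       xr = xr, xa = xa, cvr = cvr, cva = cva, lib = lib, theta = theta,
       loss_align = loss_align, loss_trans_ab = loss_trans_ab,
       loss_trans_ba = loss_trans_ba)
}

#' Co-assay pair index table of a dataset
#'
#' @param data A [timeseries_dataset()].
#' @param within Optional integer cell indices; only pairs with both
#'   endpoints inside are kept.
#' @return Integer matrix with columns `rna`, `atac` (row indices into the
#'   dataset).
#' @export
coassay_pairs <- function(data, within = NULL) {
  cells <- data$cells
  has <- which(!is.na(cells$pair_id))
  if (!is.null(within)) has <- intersect(has, within)
  rna <- has[cells$modality[has] == "RNA"]
  atac <- has[cells$modality[has] == "ATAC"]
  m <- match(cells$pair_id[rna], cells$pair_id[atac])
  keep <- !is.na(m)
  cbind(rna = rna[keep], atac = atac[m[keep]])
}

#' Train the multimodal (RNA + ATAC) model
#'
#' Stepwise adversarial optimisation with scRNA-seq as the reference
#' modality. Per minibatch round, Step 1 updates the RNA branch exactly as
#' in [train_single_modality()] (ATAC branch untouched); Step 2 copies the
#' time-relevant decoder sub-layer RNA to ATAC, freezes it, and updates the
#' ATAC encoder/decoder by the multimodal loss: Bernoulli reconstruction +
#' KL, plus `lambda_mse` times the mean squared distance between co-assay
#' pair embeddings (ATAC pulled toward RNA), plus both cross-modality
#' translation losses. Early stopping monitors the ATAC validation loss.
#'
#' @param data A [timeseries_dataset()] containing RNA and ATAC cells with
#'   co-assay `pair_id` links. RNA and ATAC cells may use different feature
#'   columns; supply them via `rna_features` / `atac_features` (default:
#'   features whose ids appear in `data$features$modality` tags, else all
#'   columns for both).
#' @param splits Output of [make_splits()].
#' @param config A [model_config()] used for both branches.
#' @param lambda_mse Weight of the embedding-alignment term (default grid:
#'   1, 100, 10000).
#' @param rna_features,atac_features Integer or logical column selectors for
#'   each modality's feature space.
#' @return An object of class `chronocell_mm_model` with elements `rna` and
#'   `atac` (each a `chronocell_model`), `lambda_mse` and `history`.
#' @export
train_multimodal <- function(data, splits, config = model_config(),
                             lambda_mse = 1,
                             rna_features = NULL, atac_features = NULL) {
  feats <- data$features
  if (is.null(rna_features)) {
    rna_features <- if ("modality" %in% names(feats)) which(feats$modality == "RNA")
    else seq_len(ncol(data$counts))
  }
  if (is.null(atac_features)) {
    atac_features <- if ("modality" %in% names(feats)) which(feats$modality == "ATAC")
    else seq_len(ncol(data$counts))
  }
  rna_train <- intersect(splits$train, which(data$cells$modality == "RNA"))
  atac_train <- intersect(splits$train, which(data$cells$modality == "ATAC"))
  rna_val <- intersect(splits$val, which(data$cells$modality == "RNA"))
  atac_val <- intersect(splits$val, which(data$cells$modality == "ATAC"))
  if (length(unique(data$cells$time_days[rna_train])) < 2L) {
    abort("RNA cells must cover at least 2 time points.")
  }
  if (length(atac_train) == 0L || length(atac_val) == 0L) {
    abort("ATAC cells required in both training and validation splits.")
  }
  pairs <- coassay_pairs(data, within = splits$train)
  if (nrow(pairs) == 0L) {
    abort("Co-assay pairs are required to train the multimodal model.")
  }
  condition_levels <- sort(unique(data$cells$condition))
  batch_levels <- sort(unique(data$cells$batch))
  n_cov <- length(condition_levels) + length(batch_levels)

  rna_model <- structure(list(config = config,
                              condition_levels = condition_levels,
                              batch_levels = batch_levels,
                              time_grid = sort(unique(data$cells$time_days[rna_train])),
                              feature_ids = feats$feature_id[rna_features],
                              feature_cols = rna_features,
                              modality = "RNA"),
                         class = "chronocell_model")
  atac_model <- structure(list(config = config,
                               condition_levels = condition_levels,
                               batch_levels = batch_levels,
                               time_grid = sort(unique(data$cells$time_days[atac_train])),
                               feature_ids = feats$feature_id[atac_features],
                               feature_cols = atac_features,
                               modality = "ATAC"),
                          class = "chronocell_model")
  model <- structure(list(rna = rna_model, atac = atac_model,
                          lambda_mse = lambda_mse, config = config),
                     class = "chronocell_mm_model")

  with_seed(config$seed, {
    pr <- init_branch(length(rna_features), n_cov, config, "zinb")
    pa <- init_branch(length(atac_features), n_cov, config, "bernoulli")
    dis_r <- init_discriminator(config, max(length(rna_model$time_grid), 2L))
    dis_a <- init_discriminator(config, max(length(atac_model$time_grid), 2L))
    opt_r <- adam_init(pr); opt_a <- adam_init(pa)
    opt_dr <- adam_init(dis_r); opt_da <- adam_init(dis_a)
    L <- config$latent_dim
    best_val <- Inf; wait <- 0L; hist <- list()
    best <- list(pr = pr, pa = pa, dis_r = dis_r, dis_a = dis_a)

    for (epoch in seq_len(config$max_epochs)) {
      kw <- config$kl_weight *
        if (config$kl_warmup > 0) min(1, epoch / config$kl_warmup) else 1
      ord_r <- sample(rna_train)
      ord_a <- sample(atac_train)
      ord_p <- pairs[sample(nrow(pairs)), , drop = FALSE]
      nb <- max(ceiling(length(ord_r) / config$batch_size),
                ceiling(length(ord_a) / config$batch_size))
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        take <- function(v, size) {
          n <- length(v)
          start <- ((bi - 1) * size) %% n
          v[(start + seq_len(min(size, n)) - 1L) %% n + 1L]
        }
        ## ---- Step 1: RNA branch (ATAC frozen) ----
        idx <- take(ord_r, config$batch_size)
        x <- as.matrix(data$counts[idx, rna_features, drop = FALSE])
        cv <- model_covariates(rna_model, data$cells$time_days[idx],
                               data$cells$condition[idx], data$cells$batch[idx])
        cls <- time_class_index(rna_model, data$cells$time_days[idx])
        enc <- branch_encode(pr, log1p(x), cv$te, cv$cond, cv$batch)
        dfw <- dis_forward(dis_r, enc$mean)
        db <- dis_backward(dis_r, dfw, cls)
        st <- adam_step(dis_r, clip_gradients(db$grads), opt_dr, lr = config$learning_rate)
        dis_r <- st$params; opt_dr <- st$state
        eps <- matrix(rnorm(length(idx) * L), length(idx), L)
        fw <- rna_forward(pr, x, cv$te, cv$cond, cv$batch, eps = eps)
        d_extra <- NULL
        if (config$adversary) {
          dfw <- dis_forward(dis_r, fw$enc$mean)
          d_extra <- -dis_backward(dis_r, dfw, cls)$dM
        }
        gr <- rna_backward(pr, fw, kw, d_extra)
        st <- adam_step(pr, clip_gradients(gr), opt_r, lr = config$learning_rate)
        pr <- st$params; opt_r <- st$state

        ## ---- Step 2: ATAC branch (RNA frozen, time layer copied) ----
        pa$dec$time <- pr$dec$time
        idx_a <- take(ord_a, config$batch_size)
        xa <- as.matrix(data$counts[idx_a, atac_features, drop = FALSE])
        cva <- model_covariates(atac_model, data$cells$time_days[idx_a],
                                data$cells$condition[idx_a], data$cells$batch[idx_a])
        cls_a <- time_class_index(atac_model, data$cells$time_days[idx_a])
        epsa <- matrix(rnorm(length(idx_a) * L), length(idx_a), L)
        fwa <- atac_forward(pa, xa, cva$te, cva$cond, cva$batch, eps = epsa)
        # ATAC time discriminator (diagnostic; trained, no generator feedback)
        if (length(atac_model$time_grid) >= 2L) {
          dfa <- dis_forward(dis_a, fwa$enc$mean)
          dba <- dis_backward(dis_a, dfa, cls_a)
          st <- adam_step(dis_a, clip_gradients(dba$grads), opt_da, lr = config$learning_rate)
          dis_a <- st$params; opt_da <- st$state
        }
        gr_a <- atac_backward(pa, fwa, kw)

        # paired terms
        np <- min(config$batch_size, nrow(ord_p))
        pstart <- ((bi - 1) * np) %% nrow(ord_p)
        prow <- ord_p[(pstart + seq_len(np) - 1L) %% nrow(ord_p) + 1L, , drop = FALSE]
        pf <- local({
          mm <- model; mm$rna$params <- pr; mm$atac$params <- pa
          pair_forward(mm, data, prow)
        })
        npair <- nrow(prow)
        # d/d m_atac of lambda * MSE
        d_ma <- model$lambda_mse * 2 * (pf$enc_a$mean - pf$enc_r$mean) / (npair * L)
        # d/d m_atac of trans_ba (RNA decoder frozen)
        gba <- zinb_loglik_grad(pf$xr, pf$dec_ba$mu,
                                matrix(pf$theta, npair, length(pf$theta), byrow = TRUE),
                                pf$dec_ba$pi)
        s <- -1 / npair
        d_rho <- (s * gba$d_mu) * pf$lib
        d_logits <- softmax_backward(pf$dec_ba$rho, d_rho)
        d_pil <- s * gba$d_pi * pf$dec_ba$pi * (1 - pf$dec_ba$pi)
        dX1 <- linear_backward(pr$dec$scale,
                               pf$dec_ba$h[[length(pf$dec_ba$h)]], d_logits)$dX
        dX2 <- linear_backward(pr$dec$dropout,
                               pf$dec_ba$h[[length(pf$dec_ba$h)]], d_pil)$dX
        d_ma <- d_ma + trunk_backward(pr$dec$trunk, pf$dec_ba$h,
                                      dX1 + dX2)$dX[, seq_len(L), drop = FALSE]
        # push d_ma through the ATAC encoder (means only)
        htop <- pf$enc_a$h[[length(pf$enc_a$h)]]
        bm <- linear_backward(pa$enc$mean, htop, d_ma)
        be <- trunk_backward(pa$enc$trunk, pf$enc_a$h, bm$dX)
        gr_pair_enc <- list(trunk = be$grads, mean = bm$grad,
                            logvar = tree_zeros(pa$enc$logvar))
        gr_a$enc <- tree_map2(`+`, gr_a$enc, gr_pair_enc)
        # trans_ab: ATAC decoder params (RNA embedding frozen)
        d_pl <- (pf$dec_ab$p - pf$xa) / npair
        topb <- pf$dec_ab$h[[length(pf$dec_ab$h)]]
        bsb <- linear_backward(pa$dec$scale, topb, d_pl)
        btb <- trunk_backward(pa$dec$trunk, pf$dec_ab$h, bsb$dX)
        d_thb <- btb$dX[, L + seq_len(ncol(pf$dec_ab$t_h)), drop = FALSE]
        btimeb <- linear_backward(pa$dec$time, pf$cva$te,
                                  d_thb * (pf$dec_ab$t_h > 0))
        gr_trans_dec <- list(time = btimeb$grad, trunk = btb$grads,
                             scale = bsb$grad)
        gr_a$dec <- tree_map2(`+`, gr_a$dec, gr_trans_dec)
        # time layer is shared from RNA and frozen during Step 2
        gr_a <- mm_zero_time_grad(gr_a)
        st <- adam_step(pa, clip_gradients(gr_a), opt_a, lr = config$learning_rate)
        pa <- st$params; opt_a <- st$state
        pa$dec$time <- pr$dec$time
        step_loss <- mean(-fwa$recon + kw * fwa$kl) +
          model$lambda_mse * pf$loss_align + pf$loss_trans_ab + pf$loss_trans_ba
        if (!is.finite(step_loss)) {
          abort(sprintf("Non-finite multimodal training loss at epoch %d.", epoch))
        }
        ep_loss <- ep_loss + step_loss
      }
      pa$dec$time <- pr$dec$time
      model$rna$params <- pr; model$rna$dis <- dis_r
      model$atac$params <- pa; model$atac$dis <- dis_a
      # joint validation loss: the ATAC branch alone converges quickly while
      # the shared time basis keeps improving with the RNA reference, so
      # stopping is monitored on both branches
      vl <- chunked_atac_val_loss(model, data, atac_val) +
        chunked_val_loss(model$rna, data, rna_val)
      if (!is.finite(vl)) abort(sprintf("Non-finite validation loss at epoch %d.", epoch))
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / nb,
                              val_loss = vl)
      if (vl < best_val - 1e-8) {
        best_val <- vl; wait <- 0L
        best <- list(pr = pr, pa = pa, dis_r = dis_r, dis_a = dis_a)
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    model$rna$params <- best$pr; model$rna$dis <- best$dis_r
    model$atac$params <- best$pa; model$atac$dis <- best$dis_a
    model$atac$params$dec$time <- best$pr$dec$time
    model$history <- dplyr::bind_rows(hist)
    model$best_val_loss <- best_val
  })
  model
}

chunked_atac_val_loss <- function(model, data, idx, chunk = 1024L) {
  tot <- 0
  for (start in seq(1, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    xa <- as.matrix(data$counts[sub, model$atac$feature_cols, drop = FALSE])
    cva <- model_covariates(model$atac, data$cells$time_days[sub],
                            data$cells$condition[sub], data$cells$batch[sub])
    fwa <- atac_forward(model$atac$params, xa, cva$te, cva$cond, cva$batch)
    tot <- tot + mean(-fwa$recon + model$config$kl_weight * fwa$kl) * length(sub)
  }
  tot / length(idx)
}

#' @export
print.chronocell_mm_model <- function(x, ...) {
  cat(sprintf("<chronocell_mm_model> RNA %d features / ATAC %d features, lambda = %g\n",
              length(x$rna$feature_ids), length(x$atac$feature_ids), x$lambda_mse))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best ATAC val loss %.3f\n",
                nrow(x$history), x$best_val_loss))
  }
  invisible(x)
}

#' @export
glance.chronocell_mm_model <- function(x, ...) {
  tibble(n_rna_features = length(x$rna$feature_ids),
         n_atac_features = length(x$atac$feature_ids),
         lambda_mse = x$lambda_mse,
         latent_dim = x$config$latent_dim,
         epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
         best_val_loss = x$best_val_loss %||% NA_real_,
         seed = x$config$seed)
}
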