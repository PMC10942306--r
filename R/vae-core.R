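#' Model configuration
#'
#' Hyperparameters of the conditional VAE. The trunk depth is fixed at two
#' hidden layers and the time-embedding dimension at 50 by default; the
#' latent dimension and the minimum time-encoding wavelength are the
#' quantities varied in the default tuning grid (see
#' [hyperparameter_grid()]).
#'
#' @param latent_dim Latent dimension (default grid: 25, 50, 100).
#' @param n_hidden_layers Number of hidden layers in encoder/decoder trunks
#'   (fixed at 2).
#' @param hidden_width Width of the hidden layers (default 512).
#' @param time_cfg A [time_encoding_config()] (default d = 50).
#' @param time_proj_width Width of the time-relevant decoder sub-layer that
#'   consumes the sinusoidal encoding; this sub-layer is what the multimodal
#'   extension shares across modalities (default 32).
#' @param kl_weight Final weight on the KL term (default 1), linearly warmed
#'   up over `kl_warmup` epochs.
#' @param kl_warmup Warm-up epochs for the KL weight (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs Maximum training epochs (default 60).
#' @param patience Early-stopping patience on the validation loss
#'   (default 5).
#' @param batch_size Minibatch size (default 256).
#' @param dis_width Hidden width of the time discriminator (default 64).
#' @param adversary Whether to subtract the discriminator loss from the
#'   generator objective (default `TRUE`); with `FALSE` the discriminator is
#'   still trained but the encoder is not optimised to fool it.
#' @param seed Integer seed; identical seed and data give bit-identical
#'   training histories.
#' @return An object of class `model_config`.
#' @export
model_config <- function(latent_dim = 50L, n_hidden_layers = 2L,
                         hidden_width = 512L,
                         time_cfg = time_encoding_config(),
                         time_proj_width = 32L,
                         kl_weight = 1, kl_warmup = 10L,
                         learning_rate = 1e-3, max_epochs = 60L,
                         patience = 5L, batch_size = 256L,
                         dis_width = 64L, adversary = TRUE, seed = 1L) {
  if (latent_dim < 1) abort("`latent_dim` must be >= 1.")
  if (n_hidden_layers != 2L) {
    warn("The trunk depth is designed for 2 hidden layers; proceeding with override.")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 time_cfg = time_cfg,
                 time_proj_width = as.integer(time_proj_width),
                 kl_weight = kl_weight, kl_warmup = as.integer(kl_warmup),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 dis_width = as.integer(dis_width),
                 adversary = isTRUE(adversary),
                 seed = as.integer(seed)),
            class = "model_config")
}

# ---- parameter initialisation -------------------------------------------

init_branch <- function(n_features, n_cov, cfg, likelihood = c("zinb", "bernoulli")) {
  likelihood <- match.arg(likelihood)
  widths <- rep(cfg$hidden_width, cfg$n_hidden_layers)
  enc_in <- n_features + cfg$time_cfg$d + n_cov
  dec_in <- cfg$latent_dim + cfg$time_proj_width + n_cov
  params <- list(
    enc = list(trunk = nn_trunk(enc_in, widths),
               mean = nn_linear(cfg$hidden_width, cfg$latent_dim),
               logvar = nn_linear(cfg$hidden_width, cfg$latent_dim)),
    dec = list(time = nn_linear(cfg$time_cfg$d, cfg$time_proj_width),
               trunk = nn_trunk(dec_in, widths),
               scale = nn_linear(cfg$hidden_width, n_features))
  )
  if (likelihood == "zinb") {
    params$dec$dropout <- nn_linear(cfg$hidden_width, n_features)
    params$log_theta <- rep(0, n_features)
  }
  params
}

init_discriminator <- function(cfg, n_classes) {
  list(trunk = nn_trunk(cfg$latent_dim, cfg$dis_width),
       out = nn_linear(cfg$dis_width, n_classes))
}

# ---- forward / backward --------------------------------------------------

branch_encode <- function(params, x_in, te, cond, batch) {
  enc_in <- cbind(x_in, te, cond, batch)
  h <- trunk_forward(params$enc$trunk, enc_in)
  m <- linear_forward(params$enc$mean, h[[length(h)]])
  lv <- pmin(pmax(linear_forward(params$enc$logvar, h[[length(h)]]), -8), 8)
  list(h = h, mean = m, logvar = lv)
}

branch_decode <- function(params, z, te, cond, batch,
                          likelihood = "zinb", lib = NULL) {
  a_t <- linear_forward(params$dec$time, te)
  t_h <- pmax(a_t, 0)
  dec_in <- cbind(z, t_h, cond, batch)
  h <- trunk_forward(params$dec$trunk, dec_in)
  top <- h[[length(h)]]
  if (likelihood == "zinb") {
    logits <- linear_forward(params$dec$scale, top)
    rho <- pmax(softmax_rows(logits), 1e-10)   # guards log(mu) and x/mu
    pi <- pmin(pmax(sigmoid(linear_forward(params$dec$dropout, top)),
                    1e-6), 1 - 1e-6)
    list(h = h, t_h = t_h, rho = rho, mu = if (is.null(lib)) rho else lib * rho,
         pi = pi)
  } else {
    p_logit <- linear_forward(params$dec$scale, top)
    list(h = h, t_h = t_h, p = sigmoid(p_logit))
  }
}

# full forward pass for one RNA minibatch; eps NULL => posterior mean
rna_forward <- function(params, x, te, cond, batch, eps = NULL) {
  lib <- pmax(rowSums(x), 1)
  enc <- branch_encode(params, log1p(x), te, cond, batch)
  z <- if (is.null(eps)) enc$mean else enc$mean + exp(0.5 * enc$logvar) * eps
  dec <- branch_decode(params, z, te, cond, batch, "zinb", lib = lib)
  theta <- exp(params$log_theta)
  ll <- zinb_loglik(x, dec$mu, theta, dec$pi)
  recon <- rowSums(ll)
  kl <- kl_gaussian(enc$mean, exp(0.5 * enc$logvar))
  list(enc = enc, dec = dec, z = z, eps = eps, lib = lib, x = x,
       te = te, cond = cond, batch = batch,
       recon = recon, kl = kl, theta = theta)
}

# gradient of mean(-recon + kl_weight * kl) wrt all branch parameters;
# d_mean_extra adds an external gradient wrt the posterior mean (adversary)
rna_backward <- function(params, fw, kl_weight, d_mean_extra = NULL) {
  b <- nrow(fw$x)
  L <- ncol(fw$enc$mean)
  theta_mat <- matrix(fw$theta, b, length(fw$theta), byrow = TRUE)
  g <- zinb_loglik_grad(fw$x, fw$dec$mu, theta_mat, fw$dec$pi)
  s <- -1 / b
  d_rho <- (s * g$d_mu) * fw$lib
  d_logits <- softmax_backward(fw$dec$rho, d_rho)
  d_pilogit <- s * g$d_pi * fw$dec$pi * (1 - fw$dec$pi)
  d_logtheta <- colSums(s * g$d_theta) * fw$theta
  top <- fw$dec$h[[length(fw$dec$h)]]
  bs <- linear_backward(params$dec$scale, top, d_logits)
  bp <- linear_backward(params$dec$dropout, top, d_pilogit)
  bt <- trunk_backward(params$dec$trunk, fw$dec$h, bs$dX + bp$dX)
  dz <- bt$dX[, seq_len(L), drop = FALSE]
  d_th <- bt$dX[, L + seq_len(ncol(fw$dec$t_h)), drop = FALSE]
  d_at <- d_th * (fw$dec$t_h > 0)
  btime <- linear_backward(params$dec$time, fw$te, d_at)
  # KL and reparameterisation
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
       dec = list(time = btime$grad, trunk = bt$grads,
                  scale = bs$grad, dropout = bp$grad),
       log_theta = d_logtheta)
}

dis_forward <- function(dis, m) {
  h <- trunk_forward(dis$trunk, m)
  logits <- linear_forward(dis$out, h[[length(h)]])
  list(h = h, p = softmax_rows(logits))
}

dis_ce <- function(p, class_idx) {
  mean(-log(pmax(p[cbind(seq_len(nrow(p)), class_idx)], 1e-12)))
}

# gradient of the CE wrt discriminator params and wrt its input embedding
dis_backward <- function(dis, fwd, class_idx) {
  b <- nrow(fwd$p)
  dlogits <- fwd$p
  dlogits[cbind(seq_len(b), class_idx)] <-
    dlogits[cbind(seq_len(b), class_idx)] - 1
  dlogits <- dlogits / b
  bo <- linear_backward(dis$out, fwd$h[[length(fwd$h)]], dlogits)
  bt <- trunk_backward(dis$trunk, fwd$h, bo$dX)
  list(grads = list(trunk = bt$grads, out = bo$grad), dM = bt$dX)
}

# ---- covariate assembly --------------------------------------------------

model_covariates <- function(model, times, condition, batch) {
  te <- sinusoidal_encode(times, model$config$time_cfg)
  cond <- encode_categories(condition, model$condition_levels)
  bat <- encode_categories(batch, model$batch_levels)
  list(te = te, cond = cond, batch = bat)
}

time_class_index <- function(model, times) {
  idx <- match(times, model$time_grid)
  if (any(is.na(idx))) {
    idx[is.na(idx)] <- vapply(times[is.na(idx)],
                              function(t) which.min(abs(model$time_grid - t)),
                              integer(1))
  }
  idx
}

# ---- public loss diagnostics --------------------------------------------

#' RNA branch loss on a set of cells
#'
#' Mean over cells of the negative ZINB reconstruction log-likelihood plus
#' `kl_weight` times the Gaussian KL term, evaluated at the posterior mean
#' (no sampling), so the value is deterministic.
#'
#' @param model A trained or initialised model (see
#'   [train_single_modality()]).
#' @param data The [timeseries_dataset()] the cells come from.
#' @param idx Integer indices of RNA cells to evaluate.
#' @param kl_weight KL weight; defaults to the model's configured value.
#' @return A list with `loss`, `recon` (mean negative log-likelihood) and
#'   `kl` (mean KL).
#' @export
loss_rna <- function(model, data, idx, kl_weight = NULL) {
  stopifnot(inherits(model, "chronocell_model"))
  if (any(data$cells$modality[idx] != "RNA")) abort("All cells must be RNA modality.")
  kl_weight <- kl_weight %||% model$config$kl_weight
  cols <- model$feature_cols %||% seq_len(ncol(data$counts))
  x <- as.matrix(data$counts[idx, cols, drop = FALSE])
  cv <- model_covariates(model, data$cells$time_days[idx],
                         data$cells$condition[idx], data$cells$batch[idx])
  fw <- rna_forward(model$params, x, cv$te, cv$cond, cv$batch, eps = NULL)
  list(loss = mean(-fw$recon + kl_weight * fw$kl),
       recon = mean(-fw$recon), kl = mean(fw$kl))
}

#' Discriminator and generator losses on a set of cells
#'
#' `loss_dis` is the cross-entropy of the time discriminator predicting each
#' cell's observed time point (as a category over the model's observed time
#' grid) from the cell embedding; `loss_gen = loss_rna - loss_dis`. With a
#' single observed time point the discriminator is disabled and
#' `loss_dis = 0` (with a warning).
#'
#' @inheritParams loss_rna
#' @return List with `loss_dis`, `loss_gen`, `loss_rna`.
#' @export
adversarial_losses <- function(model, data, idx, kl_weight = NULL) {
  lr <- loss_rna(model, data, idx, kl_weight)
  if (length(model$time_grid) < 2L) {
    warn("Single observed time point: discriminator disabled, loss_dis = 0.")
    return(list(loss_dis = 0, loss_gen = lr$loss, loss_rna = lr$loss))
  }
  cols <- model$feature_cols %||% seq_len(ncol(data$counts))
  x <- as.matrix(data$counts[idx, cols, drop = FALSE])
  cv <- model_covariates(model, data$cells$time_days[idx],
                         data$cells$condition[idx], data$cells$batch[idx])
  enc <- branch_encode(model$params, log1p(x), cv$te, cv$cond, cv$batch)
  dfw <- dis_forward(model$dis, enc$mean)
  ld <- dis_ce(dfw$p, time_class_index(model, data$cells$time_days[idx]))
  list(loss_dis = ld, loss_gen = lr$loss - ld, loss_rna = lr$loss)
}

# ---- training ------------------------------------------------------------

#' Train the single-modality (scRNA-seq) model
#'
#' Alternating adversarial optimisation: per minibatch, one discriminator
#' update (cross-entropy of predicting the observed time point from the cell
#' embedding, encoder frozen) and one generator update (reconstruction +
#' KL minus the discriminator loss, discriminator frozen). Training
#' early-stops when the validation loss has not improved for
#' `config$patience` epochs; the returned model carries the best-validation
#' parameters and the full per-epoch history. Identical `config$seed` and
#' data give identical histories.
#'
#' @param data A [timeseries_dataset()] (RNA cells are used).
#' @param splits Output of [make_splits()].
#' @param config A [model_config()].
#' @param feature_cols Columns of `data$counts` forming the RNA feature
#'   space; defaults to features tagged `modality == "RNA"` when the
#'   feature table carries a `modality` column, else all columns.
#' @return An object of class `chronocell_model`.
#' @export
train_single_modality <- function(data, splits, config = model_config(),
                                  feature_cols = NULL) {
  train_idx <- intersect(splits$train, which(data$cells$modality == "RNA"))
  val_idx <- intersect(splits$val, which(data$cells$modality == "RNA"))
  if (length(train_idx) == 0L || length(val_idx) == 0L) {
    abort("Training and validation splits must both contain RNA cells.")
  }
  if (is.null(feature_cols)) {
    feature_cols <- if ("modality" %in% names(data$features)) {
      which(data$features$modality == "RNA")
    } else seq_len(ncol(data$counts))
  }
  n_features <- length(feature_cols)
  condition_levels <- sort(unique(data$cells$condition))
  batch_levels <- sort(unique(data$cells$batch))
  time_grid <- sort(unique(data$cells$time_days[train_idx]))
  n_cov <- length(condition_levels) + length(batch_levels)
  use_dis <- length(time_grid) >= 2L
  if (!use_dis) warn("Single observed time point: discriminator disabled.")

  model <- structure(list(config = config,
                          condition_levels = condition_levels,
                          batch_levels = batch_levels,
                          time_grid = time_grid,
                          feature_ids = data$features$feature_id[feature_cols],
                          feature_cols = feature_cols,
                          modality = "RNA"),
                     class = "chronocell_model")

  with_seed(config$seed, {
    params <- init_branch(n_features, n_cov, config, "zinb")
    dis <- init_discriminator(config, max(length(time_grid), 2L))
    opt <- adam_init(params)
    opt_d <- adam_init(dis)
    model$params <- params
    model$dis <- dis

    best_val <- Inf; best_params <- params; best_dis <- dis; wait <- 0L
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      kw <- config$kl_weight *
        if (config$kl_warmup > 0) min(1, epoch / config$kl_warmup) else 1
      ord <- sample(train_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- 0; ep_dis <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, length(ord))]
        x <- as.matrix(data$counts[idx, feature_cols, drop = FALSE])
        cv <- model_covariates(model, data$cells$time_days[idx],
                               data$cells$condition[idx], data$cells$batch[idx])
        cls <- time_class_index(model, data$cells$time_days[idx])
        # discriminator step (encoder frozen)
        if (use_dis) {
          enc <- branch_encode(params, log1p(x), cv$te, cv$cond, cv$batch)
          dfw <- dis_forward(dis, enc$mean)
          db <- dis_backward(dis, dfw, cls)
          st <- adam_step(dis, clip_gradients(db$grads), opt_d, lr = config$learning_rate)
          dis <- st$params; opt_d <- st$state
        }
        # generator step (discriminator frozen)
        eps <- matrix(rnorm(length(idx) * config$latent_dim),
                      length(idx), config$latent_dim)
        fw <- rna_forward(params, x, cv$te, cv$cond, cv$batch, eps = eps)
        d_mean_extra <- NULL
        ld <- 0
        if (use_dis) {
          dfw <- dis_forward(dis, fw$enc$mean)
          ld <- dis_ce(dfw$p, cls)
          if (config$adversary) {
            db <- dis_backward(dis, dfw, cls)
            d_mean_extra <- -db$dM    # loss_gen = loss_rna - loss_dis
          }
        }
        gr <- rna_backward(params, fw, kw, d_mean_extra)
        st <- adam_step(params, clip_gradients(gr), opt, lr = config$learning_rate)
        params <- st$params; opt <- st$state
        step_loss <- mean(-fw$recon + kw * fw$kl)
        if (!is.finite(step_loss)) {
          abort(sprintf("Non-finite training loss at epoch %d.", epoch))
        }
        ep_loss <- ep_loss + step_loss; ep_dis <- ep_dis + ld
      }
      model$params <- params; model$dis <- dis
      vl <- chunked_val_loss(model, data, val_idx)
      if (!is.finite(vl)) abort(sprintf("Non-finite validation loss at epoch %d.", epoch))
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / nb,
                              dis_loss = ep_dis / nb, val_loss = vl)
      if (vl < best_val - 1e-8) {
        best_val <- vl; best_params <- params; best_dis <- dis; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    model$params <- best_params
    model$dis <- best_dis
    model$history <- dplyr::bind_rows(hist)
    model$best_val_loss <- best_val
  })
  model
}

chunked_val_loss <- function(model, data, idx, chunk = 1024L) {
  tot <- 0
  for (start in seq(1, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    lr <- loss_rna(model, data, sub)
    tot <- tot + lr$loss * length(sub)
  }
  tot / length(idx)
}

#' @export
print.chronocell_model <- function(x, ...) {
  cat(sprintf("<chronocell_model> %s branch, %d features, latent dim %d\n",
              x$modality, length(x$feature_ids), x$config$latent_dim))
  cat(sprintf("  time grid: %s\n", paste(x$time_grid, collapse = ", ")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best val loss %.3f\n",
                nrow(x$history), x$best_val_loss))
  }
  invisible(x)
}

#' @export
glance.chronocell_model <- function(x, ...) {
  tibble(modality = x$modality,
         n_features = length(x$feature_ids),
         latent_dim = x$config$latent_dim,
         n_time_points = length(x$time_grid),
         epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
         best_val_loss = x$best_val_loss %||% NA_real_,
         seed = x$config$seed)
}

#' @export
tidy.chronocell_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble())
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' Plot the training history of a model
#'
#' @param object A `chronocell_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch losses.
#' @method autoplot chronocell_model
#' @export
autoplot.chronocell_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
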