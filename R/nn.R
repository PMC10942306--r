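# Minimal dense-network machinery: linear layers, ReLU trunks, manual
# backpropagation and Adam. Parameters are nested lists of numeric arrays;
# gradients mirror the parameter structure exactly.

nn_linear <- function(n_in, n_out) {
  # He-style init; draws come from the caller's seeded RNG
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

nn_trunk <- function(n_in, widths) {
  sizes <- c(n_in, widths)
  lapply(seq_along(widths), function(i) nn_linear(sizes[i], sizes[i + 1]))
}

trunk_forward <- function(layers, X) {
  h <- vector("list", length(layers) + 1L)
  h[[1L]] <- X
  for (i in seq_along(layers)) {
    a <- sweep(h[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    h[[i + 1L]] <- pmax(a, 0)
  }
  h
}

# dH: gradient wrt the trunk output (post-ReLU). Returns grads + dX.
trunk_backward <- function(layers, h, dH) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    dA <- dH * (h[[i + 1L]] > 0)
    grads[[i]] <- list(W = crossprod(h[[i]], dA), b = colSums(dA))
    dH <- tcrossprod(dA, layers[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

linear_forward <- function(layer, X) sweep(X %*% layer$W, 2, layer$b, "+")

linear_backward <- function(layer, X, dOut) {
  list(grad = list(W = crossprod(X, dOut), b = colSums(dOut)),
       dX = tcrossprod(dOut, layer$W))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# backward through row-wise softmax: g = dL/d(prob), p = prob
softmax_backward <- function(p, g) p * (g - rowSums(g * p))

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

# rescale a gradient tree so its global L2 norm is at most `max_norm`
clip_gradients <- function(grads, max_norm = 10) {
  ss <- 0
  walk <- function(a) {
    if (is.list(a)) lapply(a, walk) else ss <<- ss + sum(a^2)
    invisible(NULL)
  }
  walk(grads)
  gn <- sqrt(ss)
  if (is.finite(gn) && gn > max_norm) {
    tree_map(function(g) g * (max_norm / gn), grads)
  } else grads
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
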