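#' Zero-inflated negative binomial log-likelihood
#'
#' Log-density of the ZINB mixture: with probability `pi` a structural zero,
#' otherwise negative binomial with mean `mu` and inverse dispersion `theta`
#' (`NB(x) = Gamma(x + theta) / (x! Gamma(theta)) * (theta / (theta + mu))^theta
#' * (mu / (theta + mu))^x`). Evaluated in log space; safe for counts up to
#' at least 1e5.
#'
#' Arguments recycle like base distribution functions; matrices are
#' supported elementwise (with `theta` recycled per feature column when
#' given as a vector of length `ncol(x)`).
#'
#' @param x Non-negative integer counts (vector or matrix).
#' @param mu Positive means.
#' @param theta Positive inverse dispersions.
#' @param pi Zero-inflation probabilities in `[0, 1]` (default 0).
#' @return Log-likelihood, same shape as `x`.
#' @examples
#' zinb_loglik(0, mu = 2, theta = 1, pi = 0.5) # log(0.5 + 0.5/3)
#' @export
zinb_loglik <- function(x, mu, theta, pi = 0) {
  if (any(x < 0) || any(x != floor(x))) abort("`x` must be non-negative integers.")
  if (any(mu <= 0) || any(theta <= 0)) abort("`mu` and `theta` must be positive.")
  if (any(pi < 0 | pi > 1)) abort("`pi` must lie in [0, 1].")
  if (is.matrix(x) && !is.matrix(theta) && length(theta) == ncol(x)) {
    theta <- matrix(theta, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  }
  log_theta_over <- log(theta) - log(theta + mu)
  log_nb <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log_theta_over + x * (log(mu) - log(theta + mu))
  # x == 0: logsumexp(log(pi), log(1 - pi) + theta * log(theta/(theta+mu)))
  log_pi <- suppressWarnings(log(pi))
  log_1mpi <- suppressWarnings(log1p(-pi))
  zero_case <- pmax(log_pi, log_1mpi + theta * log_theta_over) +
    log1p(exp(-abs(log_pi - (log_1mpi + theta * log_theta_over))))
  zero_case[pi == 0] <- (theta * log_theta_over)[pi == 0]
  zero_case[pi == 1] <- 0
  out <- log_1mpi + log_nb
  out[pi == 1] <- -Inf
  is0 <- x == 0
  if (length(out) < length(is0)) out <- rep(out, length.out = length(is0))
  if (length(zero_case) < length(is0)) zero_case <- rep(zero_case, length.out = length(is0))
  out[is0] <- zero_case[is0]
  if (is.matrix(x)) out <- matrix(out, nrow = nrow(x), ncol = ncol(x))
  out
}

# Gradients of the ZINB log-likelihood wrt (mu, theta, pi), elementwise.
# Returns list(d_mu, d_theta, d_pi) of the same shape as x.
zinb_loglik_grad <- function(x, mu, theta, pi) {
  tm <- theta + mu
  is0 <- x == 0
  # x > 0 branch
  d_mu <- x / mu - (x + theta) / tm
  d_theta <- digamma(x + theta) - digamma(theta) +
    log(theta / tm) + (mu - x) / tm
  d_pi <- -1 / (1 - pi)
  # x == 0 branch
  log_n0 <- theta * (log(theta) - log(tm))
  n0 <- exp(log_n0)
  w <- pi + (1 - pi) * n0
  d_mu0 <- (1 - pi) * n0 * (-theta / tm) / w
  d_theta0 <- (1 - pi) * n0 * (log(theta / tm) + mu / tm) / w
  d_pi0 <- (1 - n0) / w
  d_mu[is0] <- d_mu0[is0]
  d_theta[is0] <- d_theta0[is0]
  d_pi[is0] <- d_pi0[is0]
  list(d_mu = d_mu, d_theta = d_theta, d_pi = d_pi)
}

#' Bernoulli log-likelihood with probability clamping
#'
#' `x * log(p) + (1 - x) * log(1 - p)` with `p` clamped to
#' `[1e-7, 1 - 1e-7]`; the negative of the binary cross-entropy.
#'
#' @param x Binary observations (0/1).
#' @param p Success probabilities.
#' @return Log-likelihood, same shape as `x`.
#' @export
bernoulli_loglik <- function(x, p) {
  if (any(!x %in% c(0, 1))) abort("`x` must be binary (0/1).")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  x * log(p) + (1 - x) * log1p(-p)
}

#' Kullback-Leibler divergence to the standard normal prior
#'
#' Closed form for a diagonal Gaussian `N(mean, diag(std^2))` against
#' `N(0, I)`, summed over dimensions:
#' `0.5 * sum(mean^2 + std^2 - 1 - 2 log std)`.
#'
#' @param mean Numeric vector (or matrix, cells x dims).
#' @param std Positive numeric, same shape.
#' @return Scalar KL (per row when matrices are given).
#' @export
kl_gaussian <- function(mean, std) {
  if (any(std <= 0)) abort("`std` must be positive.")
  term <- 0.5 * (mean^2 + std^2 - 1 - 2 * log(std))
  if (is.matrix(term)) rowSums(term) else sum(term)
}
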