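#' Configuration for the sinusoidal time encoding
#'
#' Time is embedded as `d/2` (sine, cosine) pairs with geometrically spaced
#' frequencies, the standard transformer positional encoding generalised to a
#' continuous covariate measured in days. The frequency of pair `j` is
#' `w_j = (2 * pi / min_wavelength) / 10000^(2 * (j - 1) / d)`, so the fastest
#' component completes one cycle every `min_wavelength` days and the slowest
#' has a wavelength `10000^((d - 2) / d)` times longer.
#'
#' @param d Even integer, embedding dimension (default 50).
#' @param min_wavelength Positive real, wavelength in days of the fastest
#'   sinusoid. The default hyperparameter grid uses 1 and `2 * pi`.
#' @return An object of class `time_encoding_config`.
#' @examples
#' cfg <- time_encoding_config(d = 4)
#' sinusoidal_encode(8.25, cfg)
#' @export
time_encoding_config <- function(d = 50L, min_wavelength = 1) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 2L || d %% 2L != 0L) {
    abort("`d` must be a single even integer >= 2.")
  }
  if (!is.numeric(min_wavelength) || length(min_wavelength) != 1L ||
      !is.finite(min_wavelength) || min_wavelength <= 0) {
    abort("`min_wavelength` must be a single positive number.")
  }
  structure(list(d = d, min_wavelength = as.numeric(min_wavelength)),
            class = "time_encoding_config")
}

time_frequencies <- function(cfg) {
  j <- seq_len(cfg$d / 2L)
  (2 * pi / cfg$min_wavelength) / 10000^(2 * (j - 1) / cfg$d)
}

#' Sinusoidal encoding of time points
#'
#' @param t Numeric vector of times in days (finite).
#' @param cfg A [time_encoding_config()].
#' @return A matrix with `length(t)` rows and `cfg$d` columns; columns
#'   alternate `sin(w_j t)`, `cos(w_j t)` for `j = 1..d/2`. The squared norm
#'   of every row is `d/2`.
#' @export
sinusoidal_encode <- function(t, cfg = time_encoding_config()) {
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  w <- time_frequencies(cfg)
  arg <- outer(t, w)                      # n x d/2
  out <- matrix(0, nrow = length(t), ncol = cfg$d)
  out[, seq(1L, cfg$d, by = 2L)] <- sin(arg)
  out[, seq(2L, cfg$d, by = 2L)] <- cos(arg)
  out
}

#' One-hot encoding of a categorical vector
#'
#' @param labels Vector (character or factor) of labels.
#' @param levels Ordered character vector of permitted levels.
#' @return Binary indicator matrix, one row per label, columns in `levels`
#'   order; every row sums to one.
#' @export
encode_categories <- function(labels, levels) {
  labels <- as.character(labels)
  levels <- as.character(levels)
  bad <- setdiff(unique(labels), levels)
  if (length(bad) > 0L) {
    abort(paste0("Unknown label(s) ", paste(sQuote(bad), collapse = ", "),
                 "; known levels: ", paste(sQuote(levels), collapse = ", "), "."))
  }
  out <- matrix(0, nrow = length(labels), ncol = length(levels),
                dimnames = list(NULL, levels))
  out[cbind(seq_along(labels), match(labels, levels))] <- 1
  out
}
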