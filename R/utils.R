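# Internal numerical helpers shared across modules.

# Floor applied before every logarithm; keeps softmax algebra finite without
# perturbing normalised probabilities at working precision.
.LOG_FLOOR <- 1e-16

.log_floor <- function(p) log(pmax(p, .LOG_FLOOR))

#' Column-wise softmax at a given precision
#'
#' Rescales every column of a square matrix through a softmax with an
#' inverse-temperature (precision) multiplier: output column j equals
#' `softmax(precision * input[, j])`. At precision 0 every column is uniform;
#' as precision grows each column converges to a one-hot vector at the
#' column's argmax. This is the single functional form behind the biased
#' hashtag likelihood and both volatility-scaled transition matrices.
#'
#' @param mat Square numeric matrix with finite entries.
#' @param precision Non-negative scalar inverse temperature.
#' @return Column-stochastic matrix of the same dimension.
#' @examples
#' precision_scaled_columns(diag(2), 9)   # diagonal exp(9)/(exp(9)+1)
#' precision_scaled_columns(diag(2), 0)   # uniform columns
#' @export
precision_scaled_columns <- function(mat, precision) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || !all(is.finite(mat)))
    stop("`mat` must be a finite square matrix", call. = FALSE)
  if (!is.numeric(precision) || length(precision) != 1L || !is.finite(precision) ||
      precision < 0)
    stop("`precision` must be a non-negative finite scalar", call. = FALSE)
  z <- precision * mat
  # shift-invariant softmax per column
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# softmax of a plain vector (used for policy posteriors)
.softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Shannon entropy in nats with the 0 log 0 = 0 convention.
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.normalise <- function(p) p / sum(p)

.one_hot <- function(level, cardinality) {
  v <- numeric(cardinality)
  v[level] <- 1
  v
}

# Deterministic integer stream derivation: Lehmer-style mixing kept strictly
# below 2^31 so derived values remain valid R seeds.
.MIX_MOD <- 2147483647
.mix_seed <- function(base, ...) {
  s <- as.numeric(base) %% .MIX_MOD
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% .MIX_MOD
  }
  as.integer(s)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
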