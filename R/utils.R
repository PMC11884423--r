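# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Open (polynomial) convolution of two short nonnegative vectors.
conv_open <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Clamp a probability away from 0 and 1
#'
#' Plug-in probability estimates that enter the bivariate binomial pmf or the
#' dependence parameter alpha are clamped to `[0.5/n, 1 - 0.5/n]` (the usual
#' half-count continuity adjustment) so that degenerate observed proportions
#' (0 or 1) never produce undefined alpha or degenerate pmfs.
#'
#' @param p numeric vector of probabilities.
#' @param n sample size defining the clamp width.
#' @return clamped probabilities.
#' @export
clamp_prob <- function(p, n) {
  pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
}
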