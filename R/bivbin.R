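# Bivariate binomial model for a pair of correlated binary endpoints.
#
# Each subject has a short-term response X (probability xi) and a long-term
# response Y (probability pi) with Pearson correlation rho >= 0. The joint
# per-subject law is built hierarchically: Y ~ Bernoulli(pi), then
#   Pr(X = 1 | Y = 1) = (beta + alpha) / (1 + alpha)
#   Pr(X = 1 | Y = 0) = beta / (1 + alpha)
# with beta = xi + alpha * (xi - pi). The dependence parameter alpha is tied
# to rho through the moment identity
#   rho = [alpha / (1 + alpha)] * sqrt(pi (1 - pi) / (xi (1 - xi))),
# i.e. alpha = rho / (gamma - rho) with gamma = sqrt(pi(1-pi) / (xi(1-xi))).
# This orientation makes the per-subject Pearson correlation exactly rho and
# preserves both marginals: X ~ Bernoulli(xi) and Y ~ Bernoulli(pi).
#
# Count-level law for n subjects: Y ~ Bin(n, pi) and, given Y = y,
# X | Y = y is the sum of two independent binomials
#   Bin(y, (beta + alpha)/(1 + alpha)) + Bin(n - y, beta/(1 + alpha)),
# equivalently the sum over the dual-responder count z of the displayed
# product of binomial terms.

.bb_gamma <- function(xi, pi) sqrt(pi * (1 - pi) / (xi * (1 - xi)))

#' Supremum of the admissible endpoint correlation
#'
#' Largest `rho` for which the bivariate binomial model with marginal
#' probabilities `xi` and `pi` is admissible. The model itself only needs the
#' conditional probabilities derived from `alpha = rho / (gamma - rho)`,
#' `gamma = sqrt(pi(1-pi)/(xi(1-xi)))`, to lie in `[0, 1]`; the admissible
#' range used here additionally requires the symmetric orientation
#' (`gamma` replaced by `1/gamma`, the closed form obtained by exchanging the
#' roles of the two endpoints) to be valid. Both constraints coincide when
#' `xi == pi`. The stricter two-sided rule reproduces the documented
#' admissible range of the underlying distribution: with `xi = 0.7` and
#' `pi = 0.5`, `rho = 0.5` is admissible but `rho = 0.6` is not.
#'
#' @param xi short-term response probability, in (0, 1).
#' @param pi long-term response probability, in (0, 1).
#' @return upper bound (supremum, excluded) for `rho`; `1` when `xi == pi`.
#' @export
bb_rho_max <- function(xi, pi) {
  stopifnot(xi > 0, xi < 1, pi > 0, pi < 1)
  if (xi == pi) return(1)
  g <- .bb_gamma(xi, pi)
  # beta = xi + alpha (xi - pi) must stay in [0, 1]: a bound on alpha, hence
  # on rho, identical in form for either orientation of gamma.
  cap <- if (xi > pi) (1 - xi) / (xi - pi) else xi / (pi - xi)
  one <- function(gam) min(gam, cap * gam / (1 + cap))
  min(one(g), one(1 / g), 1)
}

#' Admissibility of a (xi, pi, rho) triple
#'
#' @inheritParams bb_rho_max
#' @param rho endpoint correlation, must satisfy `0 <= rho < 1`.
#' @return `TRUE` if the triple is admissible under the two-sided rule of
#'   [bb_rho_max()].
#' @export
bb_feasible <- function(xi, pi, rho) {
  if (rho < 0 || rho >= 1) return(FALSE)
  rho < bb_rho_max(xi, pi)
}

#' Dependence parameter alpha from the endpoint correlation
#'
#' Solves the moment identity of the per-subject construction so that the
#' Pearson correlation between the two binary endpoints equals `rho`:
#' `alpha = rho / (sqrt(pi(1-pi)/(xi(1-xi))) - rho)`. When `xi == pi` this
#' reduces to `alpha = rho / (1 - rho)`; `rho = 0` gives `alpha = 0`
#' (independence, `beta = xi`).
#'
#' @inheritParams bb_feasible
#' @return the dependence parameter `alpha >= 0`.
#' @export
bb_alpha <- function(xi, pi, rho) {
  stopifnot(xi > 0, xi < 1, pi > 0, pi < 1)
  if (!bb_feasible(xi, pi, rho)) {
    stop(sprintf(
      "correlation rho = %.3g is outside the admissible range [0, %.3g) for xi = %.3g, pi = %.3g",
      rho, bb_rho_max(xi, pi), xi, pi
    ), call. = FALSE)
  }
  if (rho == 0) return(0)
  g <- .bb_gamma(xi, pi)
  rho / (g - rho)
}

#' Construct a bivariate binomial endpoint model
#'
#' @inheritParams bb_feasible
#' @param n number of subjects (positive integer).
#' @return an object of class `bb_model`: a list with the marginal
#'   probabilities, `rho`, `n`, the derived `alpha` and
#'   `beta = xi + alpha (xi - pi)`, and the two conditional per-subject
#'   probabilities `p1 = (beta + alpha)/(1 + alpha)` (short-term response
#'   probability for a long-term responder) and `p0 = beta/(1 + alpha)`
#'   (for a long-term non-responder).
#' @export
bb_model <- function(xi, pi, rho, n) {
  stopifnot(length(n) == 1L, n >= 1, n == as.integer(n))
  alpha <- bb_alpha(xi, pi, rho)
  beta <- xi + alpha * (xi - pi)
  p1 <- (beta + alpha) / (1 + alpha)
  p0 <- beta / (1 + alpha)
  structure(
    list(xi = xi, pi = pi, rho = rho, n = as.integer(n),
         alpha = alpha, beta = beta, p1 = p1, p0 = p0),
    class = "bb_model"
  )
}

#' @export
print.bb_model <- function(x, ...) {
  cat(sprintf(
    "bivariate binomial model: n = %d, xi = %.4g, pi = %.4g, rho = %.4g (alpha = %.4g, beta = %.4g)\n",
    x$n, x$xi, x$pi, x$rho, x$alpha, x$beta
  ))
  invisible(x)
}

# pmf vector of X | Y = y over x = 0..n: convolution of Bin(y, p1) and
# Bin(n - y, p0).
.bb_cond_row <- function(y, model) {
  n <- model$n
  a <- stats::dbinom(0:y, y, model$p1)
  b <- stats::dbinom(0:(n - y), n - y, model$p0)
  conv_open(a, b)
}

#' Conditional pmf of the short-term count given the long-term count
#'
#' `Pr(X = x | Y = y)` for counts out of `n` subjects, equal to the pmf at
#' `x` of `Bin(y, p1) + Bin(n - y, p0)` (independent summands).
#'
#' @param x short-term response count(s), each in `0..n`.
#' @param y long-term response count (scalar, in `0..n`).
#' @param model a [bb_model()].
#' @return vector of probabilities, one per element of `x`.
#' @export
bb_cond_pmf <- function(x, y, model) {
  stopifnot(inherits(model, "bb_model"), length(y) == 1L,
            y >= 0, y <= model$n, all(x >= 0), all(x <= model$n))
  .bb_cond_row(y, model)[x + 1L]
}

#' Full conditional pmf matrix of X given Y
#'
#' @param model a [bb_model()].
#' @return an `(n+1) x (n+1)` matrix with entry `[y+1, x+1] = Pr(X = x | Y = y)`.
#' @export
bb_cond_matrix <- function(model) {
  n <- model$n
  t(vapply(0:n, .bb_cond_row, numeric(n + 1L), model = model))
}

#' Joint pmf of the short- and long-term counts
#'
#' `Pr(X = x, Y = y) = Bin(n, pi)(y) * Pr(X = x | Y = y)`. The x-marginal is
#' `Bin(n, xi)` and the y-marginal is `Bin(n, pi)`.
#'
#' @inheritParams bb_cond_pmf
#' @return vector of joint probabilities, one per element of `x`.
#' @export
bb_joint_pmf <- function(x, y, model) {
  stats::dbinom(y, model$n, model$pi) * bb_cond_pmf(x, y, model)
}

#' Full joint pmf matrix of (X, Y)
#'
#' @param model a [bb_model()].
#' @return matrix with entry `[y+1, x+1] = Pr(X = x, Y = y)`.
#' @export
bb_joint_matrix <- function(model) {
  stats::dbinom(0:model$n, model$n, model$pi) * bb_cond_matrix(model)
}

#' Sample endpoint counts from the bivariate binomial model
#'
#' Per-subject simulation: a long-term Bernoulli response followed by the
#' conditional short-term Bernoulli response, aggregated to the count triple
#' `(x, y, z)` where `z` is the number of dual responders. Per-subject
#' generation keeps `z` exact, which the Rao-Blackwell estimator needs.
#' Uses the current R random number stream; seed with [set.seed()].
#'
#' @param model a [bb_model()].
#' @return a list with integer counts `x`, `y`, `z` and the size `n`.
#' @export
bb_sample <- function(model) {
  n <- model$n
  y <- stats::rbinom(n, 1L, model$pi)
  p <- ifelse(y == 1L, model$p1, model$p0)
  x <- stats::rbinom(n, 1L, p)
  list(x = sum(x), y = sum(y), z = sum(x * y), n = n)
}

#' Pearson correlation of paired binary endpoints from aggregate counts
#'
#' For n per-subject binary pairs summarised by the counts `x` (short-term
#' responders), `y` (long-term responders) and `z` (dual responders), the
#' Pearson correlation is
#' `(z/n - (x/n)(y/n)) / sqrt((x/n)(1-x/n)(y/n)(1-y/n))`.
#' When either margin is degenerate (`x` or `y` in `{0, n}`) the correlation
#' is undefined and `0` is returned, a neutral plug-in that keeps downstream
#' p-value computations defined.
#'
#' @param x,y,z response counts with `0 <= z <= min(x, y)` and
#'   `z >= x + y - n`.
#' @param n number of subjects, at least 2.
#' @return Pearson correlation in `[-1, 1]`, or 0 for degenerate margins.
#' @export
pearson_rho <- function(x, y, z, n) {
  stopifnot(n >= 2, x >= 0, x <= n, y >= 0, y <= n,
            z >= max(0, x + y - n), z <= min(x, y))
  if (x == 0 || x == n || y == 0 || y == n) return(0)
  px <- x / n
  py <- y / n
  (z / n - px * py) / sqrt(px * (1 - px) * py * (1 - py))
}

# Log-likelihood in rho of the observed count triple (x, y, z) out of n,
# margins fixed: the per-subject endpoint pairs form a 2x2 table with cell
# counts (z, x - z, y - z, n - x - y + z) whose probabilities are determined
# by (xi, pi, rho) through the hierarchical construction. Vectorised over
# rho; the multinomial coefficient (constant in rho) is omitted.
.bb_loglik_rho <- function(x, y, z, n, xi, pi, rho) {
  g <- .bb_gamma(xi, pi)
  alpha <- ifelse(rho == 0, 0, rho / (g - rho))
  beta <- xi + alpha * (xi - pi)
  p1 <- pmin(pmax((beta + alpha) / (1 + alpha), 1e-12), 1 - 1e-12)
  p0 <- pmin(pmax(beta / (1 + alpha), 1e-12), 1 - 1e-12)
  cl <- function(p) pmin(pmax(p, 1e-300), 1)
  z * log(cl(pi * p1)) + (y - z) * log(cl(pi * (1 - p1))) +
    (x - z) * log(cl((1 - pi) * p0)) +
    (n - x - y + z) * log(cl((1 - pi) * (1 - p0)))
}

#' Profile likelihood estimate of the endpoint correlation
#'
#' Maximises the log-likelihood of the observed count triple `(x, y, z)`
#' under the bivariate binomial model over `rho`, with the marginal
#' probabilities held fixed at `xi` and `pi`. The per-subject endpoint pairs
#' form a 2x2 contingency table whose four cell counts are determined by the
#' triple, so the objective is the multinomial log-likelihood of that table
#' with cell probabilities driven by `rho` alone. The feasible interval
#' `[0, rho_max)` is scanned on a grid presearch (guarding against flat or
#' multimodal likelihoods near the boundary) and the best grid cell is
#' refined by bounded 1-D optimisation with tolerance `1e-6`. The fixed
#' margins are clamped per [clamp_prob()] before use, so degenerate observed
#' proportions are handled; at large `n` with margins fixed at the truth the
#' estimate is consistent for `rho`.
#'
#' @param x,y,z observed short-term, long-term and dual-responder counts out
#'   of `n`.
#' @param n number of subjects.
#' @param xi,pi fixed marginal probabilities (typically estimates).
#' @param grid_n number of presearch grid points (default 200).
#' @return the maximising correlation in `[0, rho_max)`.
#' @export
bb_profile_rho <- function(x, y, z, n, xi, pi, grid_n = 200L) {
  stopifnot(x >= 0, x <= n, y >= 0, y <= n,
            z >= max(0, x + y - n), z <= min(x, y))
  xi <- clamp_prob(xi, n)
  pi <- clamp_prob(pi, n)
  hi <- min(bb_rho_max(xi, pi), 1) * (1 - 1e-9)
  hi <- min(hi, 1 - 1e-9)
  grid <- seq(0, hi, length.out = grid_n)
  ll <- .bb_loglik_rho(x, y, z, n, xi, pi, grid)
  i <- which.max(ll)
  lo_i <- max(1L, i - 1L)
  hi_i <- min(grid_n, i + 1L)
  if (grid[hi_i] - grid[lo_i] < 1e-9) return(grid[i])
  opt <- stats::optimize(
    function(r) .bb_loglik_rho(x, y, z, n, xi, pi, r),
    interval = c(grid[lo_i], grid[hi_i]), maximum = TRUE, tol = 1e-6
  )
  if (opt$objective >= ll[i]) opt$maximum else grid[i]
}
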