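# Estimators of the response probabilities under treatment selection.
#
# Three families:
#   * MLE     — pooled proportions, ignoring the selection event (upward
#               biased for the selected group).
#   * CMAE    — MLE minus a plug-in estimate of its selection-conditional
#               bias (analytic double-sum formulas).
#   * UMVCUE  — Rao-Blackwellisation of the (selection-independent) stage-2
#               proportion given the sufficient statistics and the selection
#               event; conditionally unbiased.
#
# An estimate set carries: xi_hat for every group, pi_hat and rho_hat for the
# control and selected groups (labelled by group).

.new_estimates <- function(method, s, xi, pi, rho) {
  structure(
    list(method = method, s = s, xi = xi, pi = pi, rho = rho),
    class = "asd_estimates"
  )
}

#' @export
print.asd_estimates <- function(x, ...) {
  cat(sprintf("%s estimates (selected group s = %d)\n", toupper(x$method), x$s))
  cat("  xi_hat: ", paste(sprintf("%.4f", x$xi), collapse = " "), "\n")
  cat(sprintf("  pi_hat: control %.4f, selected %.4f\n", x$pi[1L], x$pi[2L]))
  cat(sprintf("  rho_hat: control %.4f, selected %.4f\n", x$rho[1L], x$rho[2L]))
  invisible(x)
}

#' Maximum likelihood (pooled proportion) estimates
#'
#' Pooled proportions `X_g / N_g` and `Y_g / N_g` for the continued groups
#' (control and selected), stage-1 proportions `X_g(1) / N_g(1)` for the
#' unselected treatment groups, and Pearson correlations of the pooled
#' per-subject endpoint pairs for the continued groups. These ignore the
#' selection event and are conditionally biased upward for the selected
#' group.
#'
#' @param data an [trial_data()] object.
#' @param design the [design_spec()]; defaults to the one stored in `data`.
#' @return an `asd_estimates` object with `method = "mle"`.
#' @export
estimate_mle <- function(data, design = data$design) {
  s <- data$s
  G <- design$G
  xi <- numeric(G + 1L)
  for (g in 0:G) {
    i <- g + 1L
    xi[i] <- if (g %in% c(0L, s)) {
      (data$x1[i] + data$x2[i]) / (design$n1[i] + design$n2[i])
    } else {
      data$x1[i] / design$n1[i]
    }
  }
  pi <- rho <- c(0, 0)
  for (j in 1:2) {
    g <- c(0L, s)[j]
    tt <- .totals(data, g)
    pi[j] <- tt$y / tt$n
    rho[j] <- pearson_rho(tt$x, tt$y, tt$z, tt$n)
  }
  names(pi) <- names(rho) <- c("0", as.character(s))
  .new_estimates("mle", s, xi, pi, rho)
}

# Clamp a plug-in rho into [0, rho_max) for the given (already clamped)
# margins. Negative Pearson estimates are truncated at independence; the
# model used throughout supports nonnegative correlation only.
.clamp_rho <- function(rho, xi, pi) {
  hi <- min(bb_rho_max(xi, pi), 1) * (1 - 1e-9)
  min(max(rho, 0), hi)
}

#' Selection-conditional bias of the short-term MLE
#'
#' Analytic bias `b_xi_g = E[xi_hat_MLE_g | Q = s] - xi_g` at the parameter
#' vector `xi`. For a continued group (control or selected) the stage-2
#' portion of the pooled proportion is selection-independent, giving
#' `sum_k k Pr(X_g(1) = k) Pr(Q = s | X_g(1) = k) / (N_g Pr(Q = s))
#'  + (N_g(2)/N_g) xi_g - xi_g`; for an unselected group the estimator is
#' the stage-1 proportion and the denominator is `N_g(1)` instead.
#'
#' @param g group label (0..G).
#' @param xi vector of short-term probabilities for all groups (plug-in or
#'   truth), clamped internally per [clamp_prob()].
#' @param s the selected treatment group.
#' @param design an [design_spec()] object.
#' @return the conditional bias.
#' @export
cmae_bias_xi <- function(g, xi, s, design) {
  xi_c <- clamp_prob(xi, design$n1)
  i <- g + 1L
  n1 <- design$n1[i]
  k <- 0:n1
  pk <- stats::dbinom(k, n1, xi_c[i])
  w <- prob_select_given_count(s, g, k, xi_c, design)
  pq <- prob_select(s, xi_c, design)
  num <- sum(k * pk * w)
  if (g %in% c(0L, s)) {
    N <- n1 + design$n2[i]
    num / (N * pq) + design$n2[i] / N * xi[i] - xi[i]
  } else {
    num / (n1 * pq) - xi[i]
  }
}

#' Selection-conditional bias of the long-term MLE
#'
#' Analytic bias `b_pi_g = E[pi_hat_MLE_g | Q = s] - pi_g` for a continued
#' group `g` (control or selected): a double sum over the stage-1 joint law
#' of the short- and long-term counts (bivariate binomial at
#' `(xi_g, pi_g, rho_g)`) weighted by the selection probability given the
#' short-term count, plus the selection-independent stage-2 contribution.
#' Under the treatment-only rule the control's bias is exactly zero. With
#' `rho_g = 0` the long-term count is independent of selection and the bias
#' vanishes.
#'
#' @inheritParams cmae_bias_xi
#' @param pi_g long-term probability of group `g`.
#' @param rho_g endpoint correlation of group `g`; clamped into the
#'   admissible range for the (clamped) margins.
#' @return the conditional bias.
#' @export
cmae_bias_pi <- function(g, xi, pi_g, rho_g, s, design) {
  stopifnot(g %in% c(0L, s))
  i <- g + 1L
  n1 <- design$n1[i]
  N <- n1 + design$n2[i]
  xi_c <- clamp_prob(xi, design$n1)
  pi_c <- clamp_prob(pi_g, n1)
  rho_c <- .clamp_rho(rho_g, xi_c[i], pi_c)
  w <- prob_select_given_count(s, g, 0:n1, xi_c, design)
  pq <- prob_select(s, xi_c, design)
  model <- bb_model(xi_c[i], pi_c, rho_c, n1)
  J <- bb_joint_matrix(model) # [ky+1, kx+1]
  ky <- 0:n1
  num <- sum(ky * (J %*% w))
  num / (N * pq) + design$n2[i] / N * pi_g - pi_g
}

#' Conditional mean-adjusted estimates (CMAE)
#'
#' Subtracts plug-in estimates of the selection-conditional biases from the
#' MLEs: `xi_hat_CMAE_g = xi_hat_MLE_g - b_xi_g(xi_hat_MLE)` for every group
#' and `pi_hat_CMAE_g = pi_hat_MLE_g - b_pi_g(xi_hat_MLE, pi_hat_MLE_g,
#' rho_hat_MLE_g)` for the continued groups, clipped to `[0, 1]` (bias
#' subtraction can overshoot at boundary data). The corresponding
#' correlation estimate maximises the bivariate binomial likelihood of the
#' pooled counts with the margins fixed at the CMAE values
#' ([bb_profile_rho()]).
#'
#' @inheritParams estimate_mle
#' @param profile_rho compute the profile-likelihood correlation estimates
#'   (default `TRUE`; set `FALSE` to skip and reuse the Pearson values when
#'   the correlation is not needed downstream).
#' @return an `asd_estimates` object with `method = "cmae"`.
#' @export
estimate_cmae <- function(data, design = data$design, profile_rho = TRUE) {
  s <- data$s
  G <- design$G
  mle <- estimate_mle(data, design)
  xi <- numeric(G + 1L)
  for (g in 0:G) {
    xi[g + 1L] <- mle$xi[g + 1L] - cmae_bias_xi(g, mle$xi, s, design)
  }
  xi <- pmin(pmax(xi, 0), 1)
  pi <- rho <- mle$pi
  for (j in 1:2) {
    g <- c(0L, s)[j]
    pi[j] <- mle$pi[j] -
      cmae_bias_pi(g, mle$xi, mle$pi[j], mle$rho[j], s, design)
  }
  pi <- pmin(pmax(pi, 0), 1)
  for (j in 1:2) {
    g <- c(0L, s)[j]
    tt <- .totals(data, g)
    rho[j] <- if (profile_rho) {
      bb_profile_rho(tt$x, tt$y, tt$z, tt$n, xi[g + 1L], pi[j])
    } else {
      .clamp_rho(mle$rho[j], clamp_prob(xi[g + 1L], tt$n), clamp_prob(pi[j], tt$n))
    }
  }
  .new_estimates("cmae", s, xi, pi, rho)
}

# Selection weight Pr(Q = s | W1, X_g(1) = kx) as a function of kx.
# Conditional on W1 the stage-1 counts of every competitor are fixed, so for
# g = s the weight is the deterministic win indicator honouring the
# smallest-index tie-break; for the control under the treatment-only rule it
# is constant (and cancels from the Rao-Blackwell ratio).
.w1_weight <- function(g, kx, data, design) {
  s <- data$s
  if (g != s) return(rep(1, length(kx)))
  ns <- design$n1[s + 1L]
  ok <- rep(TRUE, length(kx))
  for (h in setdiff(.rule_set(design), s)) {
    xh <- data$x1[h + 1L]
    nh <- design$n1[h + 1L]
    ok <- ok & if (h < s) xh * ns < kx * nh else xh * ns <= kx * nh
  }
  as.numeric(ok)
}

#' Rao-Blackwell (UMVCUE) estimate of a short-term probability
#'
#' Conditional expectation of the selection-independent stage-2 proportion
#' `X_g(2) / N_g(2)` given the selection event and the sufficient statistic
#' `W1` (all stage-1 counts of the competitors plus the pooled totals of the
#' continued groups). Evaluates the closed-form ratio of binomial-coefficient
#' sums with the deterministic selection-weight indicator. For the control
#' under the treatment-only rule the weights are constant and the estimator
#' collapses to the pooled MLE `X_0 / N_0`.
#'
#' @param g group label, control (0) or the selected group.
#' @param data an [trial_data()] object.
#' @param design the design; defaults to the one stored in `data`.
#' @return the estimate (exactly conditionally unbiased for `xi_g`).
#' @export
umvcue_xi <- function(g, data, design = data$design) {
  stopifnot(g %in% c(0L, data$s))
  tt <- .totals(data, g)
  if (tt$n2 == 0) stop("UMVCUE is undefined without stage-2 subjects", call. = FALSE)
  kx <- 0:tt$n1
  lc <- lchoose(tt$n1, kx) + lchoose(tt$n2, tt$x - kx)
  w <- .w1_weight(g, kx, data, design)
  keep <- is.finite(lc) & w > 0
  lc <- lc[keep]; w <- w[keep]; kxk <- kx[keep]
  m <- max(lc)
  s0 <- sum(exp(lc - m) * w)
  s1 <- sum(kxk * exp(lc - m) * w)
  tt$x / tt$n2 - s1 / (tt$n2 * s0)
}

#' Rao-Blackwell (UMVCUE) estimate of a long-term probability
#'
#' Conditional expectation of the stage-2 proportion `Y_g(2) / N_g(2)` given
#' the selection event and the sufficient statistic `W2` (which adds the
#' pooled long-term and dual-responder totals). The stage-1/stage-2 split of
#' the count triple, conditional on the pooled totals, is free of the model
#' parameters, giving a ratio of triple sums over `(kx, ky, kz)` with the
#' combinatorial coefficient
#' `c = C(n1, ky) C(n2, Y - ky) C(ky, kz) C(n1 - ky, kx - kz)
#'      C(Y - ky, Z - kz) C(n2 - Y + ky, X - kx - Z + kz)`
#' times the selection-weight indicator in `kx`. Out-of-range triples
#' contribute zero via the `C(a, b) = 0` convention.
#'
#' @inheritParams umvcue_xi
#' @return the estimate (exactly conditionally unbiased for `pi_g`).
#' @export
umvcue_pi <- function(g, data, design = data$design) {
  stopifnot(g %in% c(0L, data$s))
  tt <- .totals(data, g)
  if (tt$n2 == 0) stop("UMVCUE is undefined without stage-2 subjects", call. = FALSE)
  n1 <- tt$n1; n2 <- tt$n2
  X <- tt$x; Y <- tt$y; Z <- tt$z
  ky_r <- max(0, Y - n2):min(n1, Y)
  kx_r <- max(0, X - n2):min(n1, X)
  kz_r <- max(0, Z - n2):min(n1, Z)
  gr <- expand.grid(kx = kx_r, ky = ky_r, kz = kz_r)
  lc <- lchoose(n1, gr$ky) + lchoose(n2, Y - gr$ky) +
    lchoose(gr$ky, gr$kz) + lchoose(n1 - gr$ky, gr$kx - gr$kz) +
    lchoose(Y - gr$ky, Z - gr$kz) +
    lchoose(n2 - Y + gr$ky, X - gr$kx - Z + gr$kz)
  w <- .w1_weight(g, gr$kx, data, design)
  keep <- is.finite(lc) & w > 0
  if (!any(keep)) stop("empty support in the Rao-Blackwell sum", call. = FALSE)
  lc <- lc[keep]
  ky <- gr$ky[keep]
  m <- max(lc)
  e <- exp(lc - m)
  Y / n2 - sum(ky * e) / (n2 * sum(e))
}

#' Rao-Blackwell conditionally unbiased estimates (UMVCUE)
#'
#' UMVCUE for the short- and long-term probabilities of the control and
#' selected groups; the unselected treatment groups have no
#' selection-independent data, so their short-term estimates fall back to
#' the stage-1 MLE. Correlation estimates are profile-likelihood values at
#' the UMVCUE margins.
#'
#' @inheritParams estimate_cmae
#' @return an `asd_estimates` object with `method = "umvcue"`.
#' @export
estimate_umvcue <- function(data, design = data$design, profile_rho = TRUE) {
  s <- data$s
  mle <- estimate_mle(data, design)
  xi <- mle$xi
  pi <- rho <- mle$pi
  for (j in 1:2) {
    g <- c(0L, s)[j]
    xi[g + 1L] <- umvcue_xi(g, data, design)
    pi[j] <- umvcue_pi(g, data, design)
    tt <- .totals(data, g)
    rho[j] <- if (profile_rho) {
      bb_profile_rho(tt$x, tt$y, tt$z, tt$n, xi[g + 1L], pi[j])
    } else {
      .clamp_rho(mle$rho[j], clamp_prob(xi[g + 1L], tt$n), clamp_prob(pi[j], tt$n))
    }
  }
  .new_estimates("umvcue", s, xi, pi, rho)
}

#' Compute estimates by method name
#'
#' @param method one of `"mle"`, `"cmae"`, `"umvcue"`.
#' @inheritParams estimate_cmae
#' @return an `asd_estimates` object.
#' @export
estimate <- function(data, method = c("mle", "cmae", "umvcue"),
                     design = data$design, profile_rho = TRUE) {
  method <- match.arg(method)
  switch(method,
    mle = estimate_mle(data, design),
    cmae = estimate_cmae(data, design, profile_rho),
    umvcue = estimate_umvcue(data, design, profile_rho)
  )
}

#' Flatten an estimate set to a long-format table
#'
#' @param x an `asd_estimates` object.
#' @param ... unused.
#' @return a `data.frame` with columns `method`, `parameter`, `group`,
#'   `value`.
#' @export
as.data.frame.asd_estimates <- function(x, ...) {
  G <- length(x$xi) - 1L
  rbind(
    data.frame(method = x$method, parameter = "xi", group = 0:G, value = x$xi),
    data.frame(method = x$method, parameter = "pi",
               group = as.integer(names(x$pi)), value = unname(x$pi)),
    data.frame(method = x$method, parameter = "rho",
               group = as.integer(names(x$rho)), value = unname(x$rho))
  )
}
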