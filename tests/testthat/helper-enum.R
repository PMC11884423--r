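# Enumeration oracles used by the unit and acceptance tests. These stay
# independent of the package's own pmf/estimator code paths: probabilities
# are built from per-subject Bernoulli cells only.

# Per-subject 2x2 cell probabilities under the hierarchical construction:
# y ~ Bernoulli(pi), then x | y with probabilities p1 / p0.
enum_cells <- function(xi, pi, rho) {
  m <- bb_model(xi, pi, rho, 1L)
  c(p11 = pi * m$p1, p10 = (1 - pi) * m$p0,
    p01 = pi * (1 - m$p1), p00 = (1 - pi) * (1 - m$p0))
}

# All (x, y, z) outcomes of one stage of n subjects with their exact
# probabilities, by enumerating the 4-cell multinomial.
enum_stage <- function(n, xi, pi, rho) {
  pc <- enum_cells(xi, pi, rho)
  grid <- expand.grid(n11 = 0:n, n10 = 0:n, n01 = 0:n)
  grid$n00 <- n - grid$n11 - grid$n10 - grid$n01
  grid <- grid[grid$n00 >= 0, ]
  lp <- lgamma(n + 1) - lgamma(grid$n11 + 1) - lgamma(grid$n10 + 1) -
    lgamma(grid$n01 + 1) - lgamma(grid$n00 + 1) +
    grid$n11 * log(pc["p11"]) + grid$n10 * log(pc["p10"]) +
    grid$n01 * log(pc["p01"]) + grid$n00 * log(pc["p00"])
  data.frame(x = grid$n11 + grid$n10, y = grid$n11 + grid$n01,
             z = grid$n11, p = exp(lp))
}

# Joint pmf table of (x, y) for one stage, as an (n+1) x (n+1) matrix
# [y+1, x+1], by brute-force enumeration of all 4^n per-subject outcome
# vectors (kept deliberately naive; use small n).
enum_joint_xy <- function(n, xi, pi, rho) {
  pc <- enum_cells(xi, pi, rho)
  cells <- expand.grid(rep(list(1:4), n)) # 1=11, 2=10, 3=01, 4=00
  pr <- apply(cells, 1, function(cc) prod(pc[cc]))
  x <- apply(cells, 1, function(cc) sum(cc %in% c(1, 2)))
  y <- apply(cells, 1, function(cc) sum(cc %in% c(1, 3)))
  M <- matrix(0, n + 1, n + 1)
  for (i in seq_along(pr)) {
    M[y[i] + 1, x[i] + 1] <- M[y[i] + 1, x[i] + 1] + pr[i]
  }
  M
}

# Collapse a stage enumeration to unique (x, y, z) rows with summed
# probability.
enum_stage_u <- function(n, xi, pi, rho) {
  st <- enum_stage(n, xi, pi, rho)
  key <- paste(st$x, st$y, st$z)
  agg <- rowsum(st$p, key)
  out <- st[!duplicated(key), c("x", "y", "z")]
  out$p <- agg[match(paste(out$x, out$y, out$z), rownames(agg)), 1]
  out
}

# Full sample space of a G = 2 trial with per-group stage sizes n1, n2:
# stage 1 for control and both treatments (full x/y/z for the selected
# treatment, x only for the unselected one), stage 2 for control and the
# selected group. Returns one row per outcome with its probability and the
# selected group. Unselected-group long-term data are marginalised out.
enum_trial <- function(n1, n2, xi, pi, rho) {
  s0 <- enum_stage_u(n1, xi[1], pi[1], rho)
  t0 <- enum_stage_u(n2, xi[1], pi[1], rho)
  branches <- list()
  for (s in 1:2) {
    u <- 3 - s
    sel1 <- enum_stage_u(n1, xi[s + 1], pi[s + 1], rho)
    ts <- enum_stage_u(n2, xi[s + 1], pi[s + 1], rho)
    xu <- data.frame(x = 0:n1, p = dbinom(0:n1, n1, xi[u + 1]))
    idx <- expand.grid(i0 = seq_len(nrow(s0)), i1 = seq_len(nrow(sel1)),
                       iu = seq_len(nrow(xu)), j0 = seq_len(nrow(t0)),
                       js = seq_len(nrow(ts)))
    xs <- sel1$x[idx$i1]
    xo <- xu$x[idx$iu]
    keep <- if (s == 1) xs >= xo else xs > xo # smallest-index tie-break
    idx <- idx[keep, ]
    br <- data.frame(
      s = s,
      x1_0 = s0$x[idx$i0], y1_0 = s0$y[idx$i0], z1_0 = s0$z[idx$i0],
      x1_s = sel1$x[idx$i1], y1_s = sel1$y[idx$i1], z1_s = sel1$z[idx$i1],
      x1_u = xu$x[idx$iu],
      x2_0 = t0$x[idx$j0], y2_0 = t0$y[idx$j0], z2_0 = t0$z[idx$j0],
      x2_s = ts$x[idx$js], y2_s = ts$y[idx$js], z2_s = ts$z[idx$js],
      p = s0$p[idx$i0] * sel1$p[idx$i1] * xu$p[idx$iu] *
        t0$p[idx$j0] * ts$p[idx$js]
    )
    branches[[s]] <- br
  }
  do.call(rbind, branches)
}

# Build an asd_trial from one enumeration row.
enum_row_trial <- function(row, design) {
  G <- design$G
  s <- row$s
  u <- 3 - s
  x1 <- numeric(G + 1)
  x1[1] <- row$x1_0; x1[s + 1] <- row$x1_s; x1[u + 1] <- row$x1_u
  y1 <- z1 <- x2 <- y2 <- z2 <- rep(NA_real_, G + 1)
  y1[1] <- row$y1_0; z1[1] <- row$z1_0
  y1[s + 1] <- row$y1_s; z1[s + 1] <- row$z1_s
  x2[1] <- row$x2_0; y2[1] <- row$y2_0; z2[1] <- row$z2_0
  x2[s + 1] <- row$x2_s; y2[s + 1] <- row$y2_s; z2[s + 1] <- row$z2_s
  trial_data(design, s, x1, y1, z1, x2, y2, z2)
}

# Conditional expectation of an estimator over the enumerated space.
# `key` optionally names columns that determine the estimator's value; rows
# sharing a key are collapsed (probability summed) and the estimator is
# evaluated once per distinct key, which keeps grid sweeps fast.
enum_cond_mean <- function(rows, design, s, fun, key = NULL) {
  sub <- rows[rows$s == s, ]
  if (!is.null(key)) {
    kv <- do.call(paste, sub[, key, drop = FALSE])
    agg <- rowsum(sub$p, kv)
    sub <- sub[!duplicated(kv), ]
    sub$p <- agg[match(do.call(paste, sub[, key, drop = FALSE]), rownames(agg)), 1]
  }
  vals <- vapply(seq_len(nrow(sub)), function(i) {
    fun(enum_row_trial(sub[i, ], design))
  }, numeric(1))
  sum(vals * sub$p) / sum(sub$p)
}

# Convenience key sets: columns that determine each estimator of the
# selected group s (competitor stage-1 count plus the pooled totals that
# enter the Rao-Blackwell sums).
key_umvcue_pi <- c("x1_u", "x1_s", "x2_s", "y1_s", "y2_s", "z1_s", "z2_s")
key_umvcue_xi <- c("x1_u", "x1_s", "x2_s")
key_mle_pi <- c("y1_s", "y2_s")
key_mle_xi <- c("x1_s", "x2_s")
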