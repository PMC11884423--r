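# Selection-conditional tests and inverted confidence intervals.

# Estimate-set carrier for explicit plug-in parameters (e.g. the truth).
plugin_set <- function(s, xi, pi0, pis, rho) {
  structure(
    list(method = "plugin", s = s, xi = xi,
         pi = stats::setNames(c(pi0, pis), c("0", as.character(s))),
         rho = stats::setNames(c(rho, rho), c("0", as.character(s)))),
    class = "asd_estimates"
  )
}

test_that("conditional pmf is normalised and tilts monotonically", {
  d <- design_spec(3, n1 = 8, n2 = 8)
  td <- trial_data(d, 2, x1 = c(2, 3, 5, 1), y1 = c(3, NA, 4, NA),
                   z1 = c(2, NA, 3, NA), x2 = c(3, NA, 4, NA),
                   y2 = c(2, NA, 5, NA), z2 = c(1, NA, 3, NA))
  est <- estimate_mle(td)
  t <- 14
  k <- max(0, t - 16):min(t, 16)
  means <- vapply(c(-2, 0, 2), function(delta) {
    p <- cond_pmf_ys(k, t, delta, est, td)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    sum(k * p)
  }, numeric(1))
  # stochastically increasing in delta
  expect_true(all(diff(means) > 0))
})

test_that("constant selection weights reduce h to plain binomial coefficients", {
  # single treatment group: no competition, Pr(Q=1 | Y1) is constant and
  # h(k) must equal C(Ns, k) up to that constant (Vandermonde)
  d <- design_spec(1, n1 = 7, n2 = 9)
  td <- trial_data(d, 1, x1 = c(2, 3), y1 = c(2, 4), z1 = c(1, 2),
                   x2 = c(3, 5), y2 = c(4, 5), z2 = c(2, 3))
  est <- estimate_mle(td)
  h <- h_weights(0:16, est, td)
  expect_equal(h / h[1], choose(16, 0:16), tolerance = 1e-9)
  # rho = 0 breaks the link between selection and the long-term endpoint,
  # so the same reduction holds even with competitors
  d2 <- design_spec(2, n1 = 6, n2 = 6)
  td2 <- trial_data(d2, 1, x1 = c(1, 4, 2), y1 = c(2, 3, NA), z1 = c(1, 2, NA),
                    x2 = c(2, 3, NA), y2 = c(3, 4, NA), z2 = c(1, 2, NA))
  est2 <- plugin_set(1, c(0.2, 0.5, 0.3), 0.4, 0.55, rho = 0)
  h2 <- h_weights(0:12, est2, td2)
  expect_equal(h2 / h2[1], choose(12, 0:12), tolerance = 1e-9)
})

test_that("exact p-value reduces to the one-sided Fisher exact p", {
  d <- design_spec(1, n1 = 10, n2 = 10)
  td <- trial_data(d, 1, x1 = c(3, 5), y1 = c(2, 6), z1 = c(1, 4),
                   x2 = c(4, 6), y2 = c(3, 7), z2 = c(2, 5))
  est <- estimate_mle(td)
  est$rho[] <- 0
  tst <- conditional_test(td, est)
  ys <- 13; t <- 18
  fisher <- phyper(ys - 1, 20, 20, t, lower.tail = FALSE)
  expect_equal(tst$p_exact, fisher, tolerance = 1e-9)
  # agreement with fisher.test on the pooled 2x2 table
  ft <- fisher.test(matrix(c(13, 5, 7, 15), 2), alternative = "greater")
  expect_equal(tst$p_exact, ft$p.value, tolerance = 1e-9)
  # the supremum over delta <= 0 is attained at 0 here
  expect_equal(tst$delta_sup_exact, 0, tolerance = 1e-4)
})

test_that("conditional law matches full enumeration on the tiny design", {
  design <- design_spec(2, n1 = 2, n2 = 2)
  xi <- c(0.3, 0.5, 0.4)
  pi <- c(0.4, 0.6, 0.3)
  rho <- 0.5
  rows <- enum_trial(2, 2, xi, pi, rho)
  s <- 1
  truth <- plugin_set(s, xi, pi[1], pi[s + 1], rho)
  delta <- log(pi[s + 1] / (1 - pi[s + 1])) - log(pi[1] / (1 - pi[1]))
  sub <- rows[rows$s == s, ]
  ys_all <- sub$y1_s + sub$y2_s
  t_all <- ys_all + sub$y1_0 + sub$y2_0
  # a representative observed trial with the right selected group
  td <- enum_row_trial(sub[which(sub$x1_s == 2 & sub$x1_u == 1)[1], ], design)
  for (t in c(2, 3, 5)) {
    p_or <- vapply(max(0, t - 4):min(t, 4), function(k) {
      sum(sub$p[t_all == t & ys_all == k]) / sum(sub$p[t_all == t])
    }, numeric(1))
    p_pkg <- cond_pmf_ys(max(0, t - 4):min(t, 4), t, delta, truth, td, design)
    expect_equal(p_pkg, p_or, tolerance = 1e-10)
  }
})

test_that("mid-p never exceeds the exact p and intervals nest", {
  set.seed(31)
  sc <- scenario_spec(1, G = 3, N = 24, tau = 0.5, rho = 0.4, baseline = 0.4)
  for (r in 1:8) {
    td <- simulate_trial(sc)
    est <- estimate_mle(td)
    tst <- conditional_test(td, est)
    expect_lte(tst$p_midp, tst$p_exact + 1e-12)
    expect_true(tst$p_exact >= 0 && tst$p_exact <= 1)
    ci_e <- conditional_ci(td, est, variant = "exact")
    ci_m <- conditional_ci(td, est, variant = "midp")
    expect_lte(ci_e$lower, ci_m$lower + 1e-6)
    expect_gte(ci_e$upper, ci_m$upper - 1e-6)
    expect_lte(ci_m$lower, ci_m$upper)
  }
})

test_that("interval limits diverge at the support boundary and invert the test", {
  # all long-term responses in the selected arm, none in control:
  # ys sits at the top of its support -> upper limit +Inf
  d <- design_spec(1, n1 = 4, n2 = 4)
  td <- trial_data(d, 1, x1 = c(0, 3), y1 = c(0, 4), z1 = c(0, 3),
                   x2 = c(0, 4), y2 = c(0, 4), z2 = c(0, 4))
  est <- estimate_mle(td)
  ci <- conditional_ci(td, est, variant = "exact")
  expect_identical(ci$upper, Inf)
  expect_lt(ci$lower, Inf)
  # ys at the bottom of its support -> p = 1 and lower limit -Inf
  td2 <- trial_data(d, 1, x1 = c(0, 3), y1 = c(4, 0), z1 = c(0, 0),
                    x2 = c(0, 4), y2 = c(4, 0), z2 = c(0, 0))
  est2 <- estimate_mle(td2)
  expect_equal(conditional_test(td2, est2)$p_exact, 1, tolerance = 1e-12)
  expect_identical(conditional_ci(td2, est2, variant = "midp")$lower, -Inf)
  # duality: when the sup over delta <= 0 sits at 0, the mid-p test at
  # level alpha/2 agrees with the mid-p interval excluding 0
  set.seed(8)
  sc <- scenario_spec(5, G = 2, N = 20, tau = 0.5, rho = 0.2, delta = 0.28)
  for (r in 1:6) {
    td3 <- simulate_trial(sc)
    est3 <- estimate_mle(td3)
    tst3 <- conditional_test(td3, est3)
    if (abs(tst3$delta_sup_midp) < 1e-6) {
      ci3 <- conditional_ci(td3, est3, variant = "midp", conf = 0.95)
      expect_equal(ci3$lower > 0, tst3$p_midp <= 0.025)
    }
  }
})
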