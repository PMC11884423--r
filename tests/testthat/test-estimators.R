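# Estimator families: MLE, CMAE, UMVCUE.

# Small reference trial reused across blocks.
make_td <- function() {
  d <- design_spec(2, n1 = 6, n2 = 8)
  td <- trial_data(
    d, s = 1,
    x1 = c(1, 3, 2), y1 = c(2, 3, NA), z1 = c(1, 2, NA),
    x2 = c(2, 4, NA), y2 = c(3, 5, NA), z2 = c(1, 3, NA)
  )
  list(d = d, td = td)
}

test_that("MLE pools stages for continued groups and not for dropped ones", {
  w <- make_td()
  e <- estimate_mle(w$td)
  expect_equal(e$xi, c(3 / 14, 7 / 14, 2 / 6), tolerance = 1e-14)
  expect_equal(unname(e$pi), c(5 / 14, 8 / 14), tolerance = 1e-14)
  expect_equal(unname(e$rho[2]),
               pearson_rho(7, 8, 5, 14), tolerance = 1e-14)
  # all-zero responses give zero estimates without error
  d <- design_spec(1, n1 = 5, n2 = 5)
  td0 <- trial_data(d, 1, x1 = c(0, 0), y1 = c(0, 0), z1 = c(0, 0),
                    x2 = c(0, 0), y2 = c(0, 0), z2 = c(0, 0))
  e0 <- estimate_mle(td0)
  expect_equal(unname(e0$pi), c(0, 0))
  expect_equal(unname(e0$rho), c(0, 0)) # degenerate margins -> fallback
})

test_that("CMAE bias terms vanish where selection carries no information", {
  d <- design_spec(3, n1 = 10, n2 = 12)
  xi <- c(0.3, 0.4, 0.4, 0.4)
  # control under the treatment-only rule
  expect_equal(cmae_bias_xi(0, xi, 2, d), 0, tolerance = 1e-12)
  expect_equal(cmae_bias_pi(0, xi, 0.45, 0.5, 2, d), 0, tolerance = 1e-12)
  # rho = 0: the long-term endpoint is independent of the selection
  expect_equal(cmae_bias_pi(2, xi, 0.45, 0, 2, d), 0, tolerance = 1e-12)
  # exchangeable groups: selected-group biases are nonnegative
  expect_gt(cmae_bias_xi(2, xi, 2, d), 0)
  expect_gt(cmae_bias_pi(2, xi, 0.4, 0.5, 2, d), 0)
  # a competing (unselected) group's short-term bias is negative
  expect_lt(cmae_bias_xi(1, xi, 2, d), 0)
})

test_that("CMAE bias functions equal full-enumeration biases at the truth", {
  design <- design_spec(2, n1 = 2, n2 = 2)
  xi <- c(0.3, 0.5, 0.4)
  pi <- c(0.4, 0.6, 0.3)
  rho <- 0.5
  rows <- enum_trial(2, 2, xi, pi, rho)
  expect_equal(sum(rows$p), 1, tolerance = 1e-12)
  for (s in 1:2) {
    oracle_pi <- enum_cond_mean(rows, design, s, function(td) {
      estimate_mle(td, design)$pi[[as.character(s)]]
    }, key = key_mle_pi) - pi[s + 1]
    expect_equal(cmae_bias_pi(s, xi, pi[s + 1], rho, s, design), oracle_pi,
                 tolerance = 1e-12)
    oracle_xi <- enum_cond_mean(rows, design, s, function(td) {
      estimate_mle(td, design)$xi[s + 1]
    }, key = key_mle_xi) - xi[s + 1]
    expect_equal(cmae_bias_xi(s, xi, s, design), oracle_xi, tolerance = 1e-12)
    # unselected group's stage-1 estimator bias
    u <- 3 - s
    oracle_u <- enum_cond_mean(rows, design, s, function(td) {
      estimate_mle(td, design)$xi[u + 1]
    }, key = "x1_u") - xi[u + 1]
    expect_equal(cmae_bias_xi(u, xi, s, design), oracle_u, tolerance = 1e-12)
  }
})

test_that("CMAE subtracts the plug-in bias and clips to the unit interval", {
  w <- make_td()
  mle <- estimate_mle(w$td)
  cm <- estimate_cmae(w$td)
  b <- cmae_bias_pi(1, mle$xi, mle$pi[[2]], mle$rho[[2]], 1, w$d)
  expect_equal(cm$pi[[2]], mle$pi[[2]] - b, tolerance = 1e-12)
  expect_true(all(cm$xi >= 0 & cm$xi <= 1))
  expect_true(all(cm$pi >= 0 & cm$pi <= 1))
  # estimated nonnegative bias pulls the selected-group estimate down
  if (b >= 0) expect_lte(cm$pi[[2]], mle$pi[[2]])
})

test_that("UMVCUE is conditionally unbiased on the fully enumerable design", {
  design <- design_spec(2, n1 = 2, n2 = 2)
  xi <- c(0.3, 0.5, 0.4)
  pi <- c(0.4, 0.6, 0.3)
  rho <- 0.5
  rows <- enum_trial(2, 2, xi, pi, rho)
  for (s in 1:2) {
    mu <- enum_cond_mean(rows, design, s, function(td) umvcue_pi(s, td, design),
                         key = key_umvcue_pi)
    expect_equal(mu, pi[s + 1], tolerance = 1e-12)
    mx <- enum_cond_mean(rows, design, s, function(td) umvcue_xi(s, td, design),
                         key = key_umvcue_xi)
    expect_equal(mx, xi[s + 1], tolerance = 1e-12)
    # the MLE's conditional mean differs (upward for exchangeable groups
    # is not guaranteed here since groups differ; just non-equality)
    mle_mu <- enum_cond_mean(rows, design, s, function(td) {
      estimate_mle(td, design)$pi[[as.character(s)]]
    }, key = key_mle_pi)
    expect_gt(abs(mle_mu - pi[s + 1]), 1e-3)
  }
})

test_that("UMVCUE control estimates collapse to the pooled MLE", {
  # under the treatment-only rule the selection weight is constant in the
  # control's stage-1 count, so the Rao-Blackwell ratio reduces to X0/N0
  w <- make_td()
  expect_equal(umvcue_xi(0, w$td), 3 / 14, tolerance = 1e-12)
  expect_equal(umvcue_pi(0, w$td), 5 / 14, tolerance = 1e-12)
  e <- estimate_umvcue(w$td)
  expect_equal(e$xi[1], 3 / 14, tolerance = 1e-12)
  # unselected groups keep their stage-1 MLE
  expect_equal(e$xi[3], 2 / 6, tolerance = 1e-12)
  # degenerate selected-group data
  d <- design_spec(1, n1 = 5, n2 = 5)
  td0 <- trial_data(d, 1, x1 = c(0, 0), y1 = c(0, 0), z1 = c(0, 0),
                    x2 = c(0, 0), y2 = c(0, 0), z2 = c(0, 0))
  expect_equal(umvcue_xi(1, td0), 0)
  expect_equal(umvcue_pi(1, td0), 0)
  # no stage-2 subjects: estimator undefined
  d2 <- design_spec(1, n1 = 5, n2 = 0)
  td2 <- trial_data(d2, 1, x1 = c(1, 2), y1 = c(1, 2), z1 = c(1, 1),
                    x2 = c(0, 0), y2 = c(0, 0), z2 = c(0, 0))
  expect_error(umvcue_pi(1, td2), "stage-2")
})

test_that("estimates stay in the unit interval on boundary-heavy data", {
  d <- design_spec(2, n1 = 4, n2 = 4)
  td <- trial_data(d, 1, x1 = c(0, 4, 0), y1 = c(0, 4, NA), z1 = c(0, 4, NA),
                   x2 = c(0, 4, NA), y2 = c(0, 4, NA), z2 = c(0, 4, NA))
  for (m in c("mle", "cmae", "umvcue")) {
    e <- estimate(td, m)
    expect_true(all(e$xi >= 0 & e$xi <= 1))
    expect_true(all(e$pi >= 0 & e$pi <= 1))
    expect_true(all(e$rho >= 0 & e$rho < 1))
  }
})
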