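# Scenario grid and operating-characteristics engine.
#
# Five scenario families over a common baseline of 0.5 (alternatives) or a
# constant null:
#   1 null:  xi_g = pi_g = baseline for every group
#   2 null:  xi_g = xi_null for every group, pi_g = 0.5 (different endpoints)
#   3 "only one treatment effective": xi_g = pi_g = 0.5 + delta * 1(g = G)
#   4 "linear effect":                xi_g = pi_g = 0.5 + g * delta / G
#   5 "all treatments effective":     xi_g = pi_g = 0.5 + delta
# with delta = 0.280 when N = 50 and delta = 0.145 when N = 200 (the
# maximum difference between a treatment and the control), stage-1 size
# n1 = round(tau * N) per group (tau the information fraction), and a common
# endpoint correlation rho.

#' Define a simulation scenario
#'
#' @param id scenario family, 1-5 (see the module notes).
#' @param G number of treatment groups (2, 3 or 4 in the study grid; any
#'   `G >= 1` is accepted).
#' @param N total sample size per group.
#' @param tau information fraction in (0, 1); stage-1 size is
#'   `round(tau * N)`.
#' @param rho common endpoint correlation.
#' @param baseline constant response probability for scenario 1
#'   (default 0.1).
#' @param xi_null constant short-term probability for scenario 2
#'   (default 0.3; the long-term probability is 0.5).
#' @param delta maximum treatment-control difference for scenarios 3-5;
#'   defaults to 0.280 for `N = 50` and 0.145 for `N = 200`.
#' @param level one-sided significance level (default 0.025).
#' @return an object of class `asd_scenario` with elements `xi`, `pi`
#'   (length `G + 1`, control first), `rho`, and the implied `design`.
#' @export
scenario_spec <- function(id, G, N, tau, rho, baseline = 0.1, xi_null = 0.3,
                          delta = NULL, level = 0.025) {
  stopifnot(id %in% 1:5, tau > 0, tau < 1, N >= 2)
  if (is.null(delta)) {
    delta <- if (N == 50) 0.280 else if (N == 200) 0.145 else NA_real_
  }
  if (id %in% 3:5 && is.na(delta)) {
    stop("delta must be given explicitly when N is not 50 or 200", call. = FALSE)
  }
  g <- seq_len(G)
  pars <- switch(as.character(id),
    "1" = list(xi = rep(baseline, G + 1L), pi = rep(baseline, G + 1L)),
    "2" = list(xi = rep(xi_null, G + 1L), pi = rep(0.5, G + 1L)),
    "3" = {
      p <- c(0.5, 0.5 + delta * (g == G))
      list(xi = p, pi = p)
    },
    "4" = {
      p <- c(0.5, 0.5 + g * delta / G)
      list(xi = p, pi = p)
    },
    "5" = {
      p <- c(0.5, rep(0.5 + delta, G))
      list(xi = p, pi = p)
    }
  )
  for (gg in 0:G) {
    if (!bb_feasible(pars$xi[gg + 1L], pars$pi[gg + 1L], rho)) {
      stop(sprintf(
        "correlation rho = %.3g cannot be defined for group %d (xi = %.3g, pi = %.3g): outside the admissible range of the bivariate binomial model",
        rho, gg, pars$xi[gg + 1L], pars$pi[gg + 1L]
      ), call. = FALSE)
    }
  }
  n1 <- round(tau * N)
  design <- design_spec(G, n1 = n1, n2 = N - n1, level = level)
  structure(
    list(id = id, G = G, N = N, tau = tau, rho = rho, delta = delta,
         xi = pars$xi, pi = pars$pi, design = design),
    class = "asd_scenario"
  )
}

#' @export
print.asd_scenario <- function(x, ...) {
  cat(sprintf("scenario %d: G = %d, N = %d, tau = %.2f, rho = %.2f\n",
              x$id, x$G, x$N, x$tau, x$rho))
  cat("  xi:", sprintf("%.3f", x$xi), "\n  pi:", sprintf("%.3f", x$pi), "\n")
  invisible(x)
}

#' Simulate one trial under a scenario
#'
#' Per-subject generation from the bivariate binomial model for every
#' group's stage 1, treatment selection by the design's rule, then stage-2
#' generation for the control and selected groups only. Uses the current R
#' random number stream.
#'
#' @param scen an [scenario_spec()] object.
#' @return an [trial_data()] object.
#' @export
simulate_trial <- function(scen) {
  design <- scen$design
  G <- scen$G
  x1 <- y1 <- z1 <- rep(NA_real_, G + 1L)
  for (g in 0:G) {
    m <- bb_model(scen$xi[g + 1L], scen$pi[g + 1L], scen$rho, design$n1[g + 1L])
    cc <- bb_sample(m)
    x1[g + 1L] <- cc$x; y1[g + 1L] <- cc$y; z1[g + 1L] <- cc$z
  }
  s <- select_treatment(x1, design)
  x2 <- y2 <- z2 <- rep(NA_real_, G + 1L)
  for (g in c(0L, s)) {
    m <- bb_model(scen$xi[g + 1L], scen$pi[g + 1L], scen$rho, design$n2[g + 1L])
    cc <- bb_sample(m)
    x2[g + 1L] <- cc$x; y2[g + 1L] <- cc$y; z2[g + 1L] <- cc$z
  }
  trial_data(design, s, x1, y1, z1, x2, y2, z2)
}

# Parse "estimator.test" / "estimator.variant" combo strings.
.parse_combos <- function(x, what) {
  if (length(x) == 0L) return(data.frame(estimator = character(), kind = character()))
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop(sprintf("malformed %s combination: %s", what,
                             paste(x[bad], collapse = ", ")), call. = FALSE)
  data.frame(estimator = vapply(parts, `[[`, "", 1L),
             kind = vapply(parts, `[[`, "", 2L))
}

#' Operating characteristics by Monte Carlo simulation
#'
#' Replicates the scenario `R` times; on each replicate computes the
#' requested estimates, tests and confidence intervals, and aggregates the
#' mean and RMSE of the selected group's estimates (against the realised
#' selected group's true values), rejection rates at the design's one-sided
#' level, and coverage of the true log odds difference of the selected
#' group. Monte Carlo standard errors accompany every summary. Each
#' replicate draws from its own seed derived from `seed`, so results are
#' reproducible and independent of evaluation order.
#'
#' @param scen an [scenario_spec()] object.
#' @param R number of replicates.
#' @param estimators estimator methods to summarise
#'   (subset of `"mle"`, `"cmae"`, `"umvcue"`).
#' @param tests test combinations as `"estimator.test"` strings, e.g.
#'   `c("mle.exact", "mle.midp", "cmae.midp")`.
#' @param cis confidence-interval combinations as `"estimator.variant"`
#'   strings, e.g. `"cmae.midp"`.
#' @param seed integer seed for the replicate stream.
#' @param conf two-sided coverage of the intervals (default 0.95).
#' @param profile_rho whether estimator sets carry profile-likelihood
#'   correlation estimates (default `TRUE`); the test and CI plug-ins always
#'   use the estimator's own correlation.
#' @param keep_reps keep the per-replicate table in the result.
#' @return an object of class `asd_sim`: list with `summary` (long-format
#'   `data.frame`: `quantity`, `method`, `value`, `mc_se`, `R`), the
#'   scenario, `E_pi_s`/`E_xi_s` (exact expectations of the selected group's
#'   true probabilities), and optionally `reps`.
#' @export
run_study <- function(scen, R, estimators = c("mle", "cmae", "umvcue"),
                      tests = character(), cis = character(), seed = 1L,
                      conf = 0.95, profile_rho = TRUE, keep_reps = FALSE) {
  stopifnot(R >= 1)
  test_df <- .parse_combos(tests, "test")
  ci_df <- .parse_combos(cis, "confidence interval")
  methods <- union(estimators, union(test_df$estimator, ci_df$estimator))
  stopifnot(all(methods %in% c("mle", "cmae", "umvcue")),
            all(test_df$kind %in% c("exact", "midp")),
            all(ci_df$kind %in% c("exact", "midp")))
  design <- scen$design

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)

  delta_true <- function(g) {
    log(scen$pi[g + 1L] / (1 - scen$pi[g + 1L])) -
      log(scen$pi[1L] / (1 - scen$pi[1L]))
  }

  rows <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    td <- simulate_trial(scen)
    s <- td$s
    rec <- list(rep = r, s = s,
                xi_true = scen$xi[s + 1L], pi_true = scen$pi[s + 1L],
                delta_true = delta_true(s))
    ests <- list()
    for (m in methods) {
      e <- estimate(td, m, design, profile_rho = profile_rho)
      ests[[m]] <- e
      rec[[paste0(m, "_xi")]] <- e$xi[s + 1L]
      rec[[paste0(m, "_pi")]] <- e$pi[[as.character(s)]]
      rec[[paste0(m, "_rho")]] <- e$rho[[as.character(s)]]
    }
    if (nrow(test_df) || nrow(ci_df)) {
      for (m in unique(c(test_df$estimator, ci_df$estimator))) {
        kt <- test_df[test_df$estimator == m, , drop = FALSE]
        if (nrow(kt)) {
          tst <- conditional_test(td, ests[[m]], design)
          for (kind in kt$kind) {
            p <- if (kind == "exact") tst$p_exact else tst$p_midp
            rec[[paste0(m, ".", kind, "_reject")]] <- as.numeric(p <= design$level)
          }
        }
        kc <- ci_df[ci_df$estimator == m, , drop = FALSE]
        for (kind in kc$kind) {
          ci <- conditional_ci(td, ests[[m]], design, conf = conf, variant = kind)
          dt <- rec$delta_true
          rec[[paste0(m, ".", kind, "_cover")]] <-
            as.numeric(ci$lower <= dt && dt <= ci$upper)
        }
      }
    }
    rows[[r]] <- rec
  }
  reps <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))

  summ <- list()
  add <- function(quantity, method, v, se) {
    summ[[length(summ) + 1L]] <<- data.frame(
      quantity = quantity, method = method, value = v, mc_se = se, R = R)
  }
  for (m in intersect(c("mle", "cmae", "umvcue"), estimators)) {
    for (par in c("xi", "pi")) {
      est <- reps[[paste0(m, "_", par)]]
      tru <- reps[[paste0(par, "_true")]]
      add(paste0("mean_", par), m, mean(est), stats::sd(est) / sqrt(R))
      se2 <- (est - tru)^2
      rmse <- sqrt(mean(se2))
      add(paste0("rmse_", par), m, rmse,
          stats::sd(se2) / (2 * max(rmse, 1e-12) * sqrt(R)))
    }
    rh <- reps[[paste0(m, "_rho")]]
    add("mean_rho", m, mean(rh), stats::sd(rh) / sqrt(R))
  }
  for (j in seq_len(nrow(test_df))) {
    key <- paste0(test_df$estimator[j], ".", test_df$kind[j])
    rj <- reps[[paste0(key, "_reject")]]
    p <- mean(rj)
    add("reject_pct", key, 100 * p, 100 * sqrt(p * (1 - p) / R))
  }
  for (j in seq_len(nrow(ci_df))) {
    key <- paste0(ci_df$estimator[j], ".", ci_df$kind[j])
    cv <- reps[[paste0(key, "_cover")]]
    p <- mean(cv)
    add("coverage_pct", key, 100 * p, 100 * sqrt(p * (1 - p) / R))
  }
  out <- list(
    summary = do.call(rbind, summ),
    scenario = scen, seed = seed, R = R,
    E_xi_s = expected_selected_value(scen$xi[-1L], scen$xi, design),
    E_pi_s = expected_selected_value(scen$pi[-1L], scen$xi, design)
  )
  if (keep_reps) out$reps <- reps
  structure(out, class = "asd_sim")
}

#' @export
print.asd_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("simulation study: scenario %d, G = %d, N = %d, tau = %.2f, rho = %.2f, R = %d\n",
              s$id, s$G, s$N, s$tau, s$rho, x$R))
  cat(sprintf("  exact E[xi_s] = %.4f, E[pi_s] = %.4f\n", x$E_xi_s, x$E_pi_s))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
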