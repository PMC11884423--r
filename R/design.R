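# Trial design, selection rule, and selection-probability machinery.
#
# Groups are labelled g = 0 (control), 1..G (treatments). Internally vectors
# indexed over groups use position g + 1. Stage-1 response rates are compared
# as exact integer cross-products, never as floating ratios, so ties are
# detected exactly and resolved to the smallest group index (lowest dose).

#' Specify a two-stage seamless design
#'
#' @param G number of treatment groups (>= 1).
#' @param n1 stage-1 sample size per group; scalar or vector of length
#'   `G + 1` ordered control first.
#' @param n2 stage-2 sample size for the groups that continue (control and
#'   the selected treatment); scalar or vector of length `G + 1`.
#' @param rule selection-rule variant: `"treatment"` selects the treatment
#'   with the highest stage-1 short-term response rate; `"control-inclusive"`
#'   additionally lets the control "win", signalling an early stop for
#'   lack of benefit.
#' @param level one-sided significance level for the final test
#'   (default 0.025).
#' @return an object of class `asd_design`.
#' @export
design_spec <- function(G, n1, n2, rule = c("treatment", "control-inclusive"),
                        level = 0.025) {
  rule <- match.arg(rule)
  stopifnot(length(G) == 1L, G >= 1, G == as.integer(G))
  n1 <- as.integer(rep_len(n1, G + 1L))
  n2 <- as.integer(rep_len(n2, G + 1L))
  stopifnot(all(n1 > 0), all(n2 >= 0), level > 0, level < 0.5)
  structure(
    list(G = as.integer(G), n1 = n1, n2 = n2, rule = rule, level = level),
    class = "asd_design"
  )
}

#' @export
print.asd_design <- function(x, ...) {
  cat(sprintf(
    "seamless two-stage design: G = %d treatment groups, rule = %s, level = %g\n",
    x$G, x$rule, x$level
  ))
  cat("  stage-1 sizes:", x$n1, "\n  stage-2 sizes:", x$n2, "\n")
  invisible(x)
}

# Indices (0-based labels) of the groups eligible for selection.
.rule_set <- function(design) {
  if (design$rule == "treatment") seq_len(design$G) else 0:design$G
}

#' Apply the selection rule to stage-1 short-term counts
#'
#' Returns the index of the group with the highest stage-1 short-term
#' response rate among the rule's eligible set, ties resolved to the
#' smallest index. Under the control-inclusive rule a return value of 0
#' means the control had the (weakly) highest rate and the trial stops for
#' lack of benefit.
#'
#' @param x1 integer vector of stage-1 short-term response counts for all
#'   groups (control first, length `G + 1`).
#' @param design an [design_spec()] object.
#' @return selected group label (integer; 1..G, or 0 only under the
#'   control-inclusive rule).
#' @export
select_treatment <- function(x1, design) {
  stopifnot(length(x1) == design$G + 1L, all(x1 >= 0), all(x1 <= design$n1))
  cand <- .rule_set(design)
  best <- cand[1L]
  for (g in cand[-1L]) {
    # g beats current best only with a strictly higher rate (exact compare)
    if (x1[g + 1L] * design$n1[best + 1L] > x1[best + 1L] * design$n1[g + 1L]) {
      best <- g
    }
  }
  best
}

# Largest integer count c such that c / nh  <  k / ns  (strict = TRUE)
# or c / nh <= k / ns (strict = FALSE); -1 when no count qualifies.
.rate_bound <- function(k, ns, nh, strict) {
  if (strict) {
    if (k * nh <= 0) return(-1)
    (k * nh - 1) %/% ns
  } else {
    (k * nh) %/% ns
  }
}

# For each k in 0..n1[s], probability that competitor h loses to the
# candidate s holding count k (accounting for the smallest-index tie-break).
.win_prob_h <- function(s, h, k, xi, design) {
  ns <- design$n1[s + 1L]
  nh <- design$n1[h + 1L]
  strict <- h < s # lower-indexed competitor wins ties
  bounds <- vapply(k, .rate_bound, numeric(1), ns = ns, nh = nh, strict = strict)
  stats::pbinom(bounds, nh, xi[h + 1L])
}

# Product over all competitors of the per-competitor win probabilities,
# for k = 0..n1[s]. Optionally excludes one competitor.
.win_prob_vec <- function(s, xi, design, exclude = NULL) {
  k <- 0:design$n1[s + 1L]
  w <- rep(1, length(k))
  for (h in setdiff(.rule_set(design), c(s, exclude))) {
    w <- w * .win_prob_h(s, h, k, xi, design)
  }
  w
}

#' Probability that a given group is selected
#'
#' `Pr(Q = s)` under independent stage-1 counts `X_g ~ Bin(n1_g, xi_g)`,
#' computed exactly as a sum over the candidate's count of binomial pmf
#' times the product of the competitors' losing probabilities (honouring the
#' smallest-index tie-break). Probabilities over the rule's eligible set sum
#' to one.
#'
#' @param s group label whose selection probability is wanted.
#' @param xi vector of short-term response probabilities for all groups
#'   (control first, length `G + 1`).
#' @param design an [design_spec()] object.
#' @return `Pr(Q = s)`.
#' @export
prob_select <- function(s, xi, design) {
  stopifnot(s %in% .rule_set(design), length(xi) == design$G + 1L)
  k <- 0:design$n1[s + 1L]
  sum(stats::dbinom(k, design$n1[s + 1L], xi[s + 1L]) *
        .win_prob_vec(s, xi, design))
}

#' Selection probability conditional on one group's stage-1 count
#'
#' `Pr(Q = s | X_g(1) = k)`. For `g = s` this is the closed-form product of
#' the competitors' losing probabilities at count `k`. For a group outside
#' the rule's eligible set (the control under the treatment-only rule) the
#' count carries no information and the unconditional `Pr(Q = s)` is
#' returned. For any other competitor the remaining groups are summed out.
#'
#' @param s selected group label.
#' @param g group label being conditioned on.
#' @param k count(s) for group `g`'s stage-1 short-term responses.
#' @inheritParams prob_select
#' @return vector of probabilities, one per element of `k`.
#' @export
prob_select_given_count <- function(s, g, k, xi, design) {
  stopifnot(s %in% .rule_set(design), all(k >= 0), all(k <= design$n1[g + 1L]))
  if (!(g %in% .rule_set(design))) {
    return(rep(prob_select(s, xi, design), length(k)))
  }
  if (g == s) {
    return(.win_prob_vec(s, xi, design)[k + 1L])
  }
  # s must beat g at g's count k, and all remaining competitors at s's count.
  ks <- 0:design$n1[s + 1L]
  base <- stats::dbinom(ks, design$n1[s + 1L], xi[s + 1L]) *
    .win_prob_vec(s, xi, design, exclude = g)
  ns <- design$n1[s + 1L]
  ng <- design$n1[g + 1L]
  strict <- g < s
  vapply(k, function(kk) {
    ok <- if (strict) kk * ns < ks * ng else kk * ns <= ks * ng
    sum(base[ok])
  }, numeric(1))
}

#' Exact expectation of a per-treatment value at the selected group
#'
#' Computes `sum_s values[s] * Pr(Q = s)` over the treatment groups by exact
#' enumeration (no simulation). With all values equal to a constant the
#' result is that constant. Used for the analytic expectation of the
#' selected group's true response probability, the reference point for bias
#' and RMSE summaries.
#'
#' @param values numeric vector with one value per treatment group
#'   (`length G`, group 1 first).
#' @inheritParams prob_select
#' @return the exact expectation.
#' @export
expected_selected_value <- function(values, xi, design) {
  stopifnot(length(values) == design$G)
  sum(vapply(seq_len(design$G), function(s) {
    values[s] * prob_select(s, xi, design)
  }, numeric(1)))
}
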