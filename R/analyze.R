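# Analysis orchestration and config-file plumbing.
#
# A trial record or a simulation request can be supplied as a YAML or JSON
# config file; results are written as long-format CSV. Every number in the
# output is produced by a library call; formatting only rounds.

#' Full analysis of one observed trial
#'
#' For each requested estimator: parameter estimates, exact and mid-p
#' p-values, and exact and mid-p confidence intervals for the log odds
#' difference between the selected and control groups.
#'
#' @param data an [trial_data()] object.
#' @param design the design; defaults to the one stored in `data`.
#' @param methods estimators to run (subset of `"mle"`, `"cmae"`,
#'   `"umvcue"`).
#' @param conf two-sided coverage of the intervals (default 0.95).
#' @return an object of class `asd_analysis`: list with `estimates`
#'   (long-format `data.frame`) and `inference` (one row per method with
#'   p-values and interval limits).
#' @export
analyze_trial <- function(data, design = data$design,
                          methods = c("mle", "cmae", "umvcue"), conf = 0.95) {
  stopifnot(all(methods %in% c("mle", "cmae", "umvcue")))
  est_rows <- list()
  inf_rows <- list()
  for (m in methods) {
    e <- estimate(data, m, design)
    est_rows[[m]] <- as.data.frame(e)
    tst <- conditional_test(data, e, design)
    ci_e <- conditional_ci(data, e, design, conf = conf, variant = "exact")
    ci_m <- conditional_ci(data, e, design, conf = conf, variant = "midp")
    inf_rows[[m]] <- data.frame(
      method = m, p_exact = tst$p_exact, p_midp = tst$p_midp,
      ci_exact_lower = ci_e$lower, ci_exact_upper = ci_e$upper,
      ci_midp_lower = ci_m$lower, ci_midp_upper = ci_m$upper,
      conf = conf, level = design$level
    )
  }
  structure(
    list(estimates = do.call(rbind, est_rows),
         inference = do.call(rbind, inf_rows)),
    class = "asd_analysis"
  )
}

#' @export
print.asd_analysis <- function(x, ...) {
  est <- x$estimates
  cat("parameter estimates (probabilities as %):\n")
  for (m in unique(est$method)) {
    sub <- est[est$method == m & est$parameter == "pi", ]
    cat(sprintf("  %-7s pi_hat: %s\n", toupper(m),
                paste(sprintf("group %d: %.1f%%", sub$group, 100 * sub$value),
                      collapse = ", ")))
  }
  cat("inference on the log odds difference Delta_s:\n")
  inf <- x$inference
  for (i in seq_len(nrow(inf))) {
    cat(sprintf(
      "  %-7s exact p = %.4g, mid-p = %.4g; %g%% CI exact [%.2f, %.2f], mid-p [%.2f, %.2f]\n",
      toupper(inf$method[i]), inf$p_exact[i], inf$p_midp[i], 100 * inf$conf[i],
      inf$ci_exact_lower[i], inf$ci_exact_upper[i],
      inf$ci_midp_lower[i], inf$ci_midp_upper[i]))
  }
  invisible(x)
}

# Read a YAML (.yml/.yaml) or JSON (.json) config file into a list.
.read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML (.yml/.yaml) or JSON (.json)", call. = FALSE)
  }
}

.cfg_get <- function(cfg, name, default = NULL, required = is.null(default)) {
  if (!is.null(cfg[[name]])) return(cfg[[name]])
  if (required) stop(sprintf("config field '%s' is required", name), call. = FALSE)
  default
}

# Build design + trial data from the flat record in a config list.
# Field names: G, n1, n2, rule, level, s, x1, y1, z1, x2, y2, z2; count
# vectors are ordered control first and use NA (or ~ in YAML) for
# unobserved entries.
.config_trial <- function(cfg) {
  design <- design_spec(
    G = .cfg_get(cfg, "G"),
    n1 = .cfg_get(cfg, "n1"),
    n2 = .cfg_get(cfg, "n2"),
    rule = .cfg_get(cfg, "rule", "treatment"),
    level = .cfg_get(cfg, "level", 0.025)
  )
  na_num <- function(v) {
    v <- unlist(v)
    suppressWarnings(as.numeric(v))
  }
  trial_data(
    design, s = .cfg_get(cfg, "s"),
    x1 = na_num(.cfg_get(cfg, "x1")), y1 = na_num(.cfg_get(cfg, "y1")),
    z1 = na_num(.cfg_get(cfg, "z1")), x2 = na_num(.cfg_get(cfg, "x2")),
    y2 = na_num(.cfg_get(cfg, "y2")), z2 = na_num(.cfg_get(cfg, "z2"))
  )
}

#' Analyse a trial described by a config file
#'
#' Reads a YAML/JSON record of observed counts, validates it, runs
#' [analyze_trial()], and optionally writes two CSV files
#' (`<out>_estimates.csv`, `<out>_inference.csv`).
#'
#' @param config path to a config file, or an equivalent named list.
#' @param out optional output path stem for CSV files.
#' @param quiet suppress the printed report.
#' @return the `asd_analysis` object, invisibly when `quiet = FALSE`.
#' @export
run_analyze_config <- function(config, out = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) .read_config(config) else config
  td <- .config_trial(cfg)
  res <- analyze_trial(
    td, methods = .cfg_get(cfg, "methods", c("mle", "cmae", "umvcue")),
    conf = .cfg_get(cfg, "conf", 0.95)
  )
  if (!is.null(out)) {
    utils::write.csv(res$estimates, paste0(out, "_estimates.csv"), row.names = FALSE)
    utils::write.csv(res$inference, paste0(out, "_inference.csv"), row.names = FALSE)
  }
  if (!quiet) print(res)
  invisible(res)
}

#' Run a simulation study described by a config file
#'
#' Config fields: `scenario` (id), `G`, `N`, `tau`, `rho`, `R`, `seed`, and
#' optionally `baseline`, `xi_null`, `delta`, `estimators`, `tests`, `cis`,
#' `conf`, `level`. Writes the long-format summary (with Monte Carlo
#' standard errors) to `<out>.csv` when `out` is given.
#'
#' @inheritParams run_analyze_config
#' @return the `asd_sim` object, invisibly when `quiet = FALSE`.
#' @export
run_simulate_config <- function(config, out = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) .read_config(config) else config
  R <- .cfg_get(cfg, "R")
  if (!is.numeric(R) || R < 1) stop("config field 'R' must be a positive replicate count", call. = FALSE)
  scen <- scenario_spec(
    id = .cfg_get(cfg, "scenario"), G = .cfg_get(cfg, "G"),
    N = .cfg_get(cfg, "N"), tau = .cfg_get(cfg, "tau"),
    rho = .cfg_get(cfg, "rho"),
    baseline = .cfg_get(cfg, "baseline", 0.1),
    xi_null = .cfg_get(cfg, "xi_null", 0.3),
    delta = .cfg_get(cfg, "delta", required = FALSE),
    level = .cfg_get(cfg, "level", 0.025)
  )
  res <- run_study(
    scen, R = R,
    estimators = .cfg_get(cfg, "estimators", c("mle", "cmae", "umvcue")),
    tests = .cfg_get(cfg, "tests", character(), required = FALSE),
    cis = .cfg_get(cfg, "cis", character(), required = FALSE),
    seed = .cfg_get(cfg, "seed", 1L),
    conf = .cfg_get(cfg, "conf", 0.95)
  )
  if (!is.null(out)) {
    utils::write.csv(res$summary, paste0(out, ".csv"), row.names = FALSE)
  }
  if (!quiet) print(res)
  invisible(res)
}
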