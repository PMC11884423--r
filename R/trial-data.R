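# Observed trial data container and validation.

#' Assemble observed counts from a two-stage seamless trial
#'
#' Counts are supplied as vectors over all groups (control first, length
#' `G + 1`), with `NA` for quantities that are unobserved (stage-2 counts
#' and long-term counts of unselected treatment groups). The control group
#' and the selected group must have complete short-term, long-term and
#' dual-responder counts for both stages.
#'
#' @param design an [design_spec()] object.
#' @param s selected treatment group label (1..G).
#' @param x1 stage-1 short-term response counts, all groups.
#' @param y1 stage-1 long-term response counts (control and selected group
#'   required).
#' @param z1 stage-1 dual-responder counts (both endpoints responded).
#' @param x2,y2,z2 stage-2 counts for the control and selected group.
#' @return an object of class `asd_trial`.
#' @export
trial_data <- function(design, s, x1, y1, z1, x2, y2, z2) {
  G <- design$G
  as_counts <- function(v, what) {
    v <- rep_len(as.numeric(v), G + 1L)
    if (any(v < 0, na.rm = TRUE)) {
      stop(sprintf("negative %s count", what), call. = FALSE)
    }
    v
  }
  x1 <- as_counts(x1, "x1"); y1 <- as_counts(y1, "y1"); z1 <- as_counts(z1, "z1")
  x2 <- as_counts(x2, "x2"); y2 <- as_counts(y2, "y2"); z2 <- as_counts(z2, "z2")

  if (!(s %in% seq_len(G))) {
    stop("selected group must be a treatment group (trials stopped at the interim are not analysed)",
         call. = FALSE)
  }
  if (any(is.na(x1))) stop("stage-1 short-term counts are required for all groups", call. = FALSE)
  if (any(x1 > design$n1)) stop("x1 exceeds the stage-1 sample size", call. = FALSE)
  if (select_treatment(x1, design) != s) {
    stop("selected group s is inconsistent with the selection rule applied to x1",
         call. = FALSE)
  }
  for (g in c(0L, s)) {
    i <- g + 1L
    if (anyNA(c(x2[i], y1[i], y2[i], z1[i], z2[i]))) {
      stop(sprintf("complete stage-1 and stage-2 counts are required for group %d", g),
           call. = FALSE)
    }
    chk <- function(x, y, z, n, stage) {
      if (x > n || y > n) {
        stop(sprintf("group %d stage-%d counts exceed the sample size", g, stage), call. = FALSE)
      }
      if (z > min(x, y) || z < max(0, x + y - n)) {
        stop(sprintf(
          "group %d stage-%d dual-responder count z violates max(0, x + y - n) <= z <= min(x, y)",
          g, stage), call. = FALSE)
      }
    }
    chk(x1[i], y1[i], z1[i], design$n1[i], 1L)
    chk(x2[i], y2[i], z2[i], design$n2[i], 2L)
  }
  structure(
    list(design = design, s = as.integer(s),
         x1 = x1, y1 = y1, z1 = z1, x2 = x2, y2 = y2, z2 = z2),
    class = "asd_trial"
  )
}

# Pooled totals for a continued group g (0 or s).
.totals <- function(data, g) {
  i <- g + 1L
  d <- data$design
  list(
    x = data$x1[i] + data$x2[i],
    y = data$y1[i] + data$y2[i],
    z = data$z1[i] + data$z2[i],
    n = d$n1[i] + d$n2[i],
    n1 = d$n1[i], n2 = d$n2[i]
  )
}

#' @export
print.asd_trial <- function(x, ...) {
  d <- x$design
  cat(sprintf("seamless trial data: G = %d, selected group s = %d\n", d$G, x$s))
  cat("  stage-1 short-term counts:", x$x1, "/", d$n1, "\n")
  for (g in c(0L, x$s)) {
    tt <- .totals(x, g)
    cat(sprintf("  group %d totals: X = %d/%d, Y = %d/%d, Z = %d\n",
                g, tt$x, tt$n, tt$y, tt$n, tt$z))
  }
  invisible(x)
}
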