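# Large-sample Z-tests used to annotate between-timepoint differences in
# feature means and cluster proportions. Two-sided throughout; no
# multiple-testing correction is applied (pairwise comparisons are reported
# individually), a deliberate limitation documented in the vignette.

#' Two-sample Z-test for means (summary statistics)
#'
#' `z = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with a two-sided
#' p-value from the standard normal -- the large-sample test appropriate
#' when both groups have at least ~30 observations (a warning is issued
#' below that). Zero pooled variance gives z = 0, p = 1 when the means are
#' equal and an infinite-z flag (p = 0) when they differ.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return object of class `ztest_result`: `statistic`, `p_value`,
#'   `test_kind`, `n1`, `n2`, `infinite_z`.
#' @export
ztest_two_means <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 1, n2 >= 1)
  if (n1 < 30 || n2 < 30) {
    warning("group sizes below 30: the large-sample normal approximation may be poor")
  }
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  if (se == 0) {
    if (mean1 == mean2) {
      z <- 0; p <- 1; inf_z <- FALSE
    } else {
      z <- sign(mean1 - mean2) * Inf; p <- 0; inf_z <- TRUE
    }
  } else {
    z <- (mean1 - mean2) / se
    p <- 2 * stats::pnorm(-abs(z))
    inf_z <- FALSE
  }
  structure(list(statistic = z, p_value = p, test_kind = "two_mean",
                 n1 = n1, n2 = n2, infinite_z = inf_z),
            class = "ztest_result")
}

#' Two-sample Z-test for proportions (pooled)
#'
#' Pooled-proportion z statistic
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p = (x1+x2)/(n1+n2)`,
#' two-sided p-value -- the proportion analogue used to compare per-cluster
#' cell fractions between timepoints.
#'
#' @param x1,n1 successes and size of group 1 (`0 <= x1 <= n1`).
#' @param x2,n2 successes and size of group 2.
#' @return object of class `ztest_result`.
#' @export
ztest_two_proportions <- function(x1, n1, x2, n2) {
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) {
    stop("successes must lie in [0, n]")
  }
  if (n1 < 30 || n2 < 30) {
    warning("group sizes below 30: the large-sample normal approximation may be poor")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (p1 == p2) {
      z <- 0; p <- 1; inf_z <- FALSE
    } else {
      z <- sign(p1 - p2) * Inf; p <- 0; inf_z <- TRUE
    }
  } else {
    z <- (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
    inf_z <- FALSE
  }
  structure(list(statistic = z, p_value = p, test_kind = "two_proportion",
                 n1 = n1, n2 = n2, infinite_z = inf_z),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("<ztest_result> %s: z = %.4g, p = %.4g (%s), n1 = %d, n2 = %d\n",
              x$test_kind, x$statistic, x$p_value,
              significance_labels(x$p_value), x$n1, x$n2))
  invisible(x)
}

#' Significance label for a p-value
#'
#' `NS` for p >= 0.05 (the boundary counts as NS), `*` below 0.05, `**`
#' below 0.01, `***` below 0.001.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of labels.
#' @export
significance_labels <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}
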