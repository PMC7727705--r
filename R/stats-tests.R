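#' Welch two-sample t-test from summary statistics
#'
#' Two-sided Welch test computed from group means, standard deviations and
#' sizes, with the Welch-Satterthwaite degrees of freedom.  Used to compare
#' class-mean correlation times between receptor states when only summarized
#' replica data are available.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welch_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (nm in c("n1", "n2"))
    stopifnot_scalar(get(nm), nm, lower = 2)
  for (nm in c("sd1", "sd2"))
    stopifnot_scalar(get(nm), nm, lower = 0)
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  if (se1 + se2 == 0) {
    # zero variance in both groups: equal means give p = 1 by convention,
    # unequal means are infinitely significant
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Paired t-test on raw replicate pairs
#'
#' One-sample t-test on the within-pair differences (two-sided), as used when
#' the same simulation run of a segment is compared between two receptor
#' states.  Delegates to [stats::t.test()].  All-zero differences return
#' `t = 0, p = 1`; nonzero constant differences are degenerate (zero variance)
#' and are flagged with `p = 0` and infinite `t`.
#'
#' @param pairs two-column matrix or data.frame of paired observations (x, y).
#' @return list with `t`, `df`, `p` and optional `flag`.
#' @export
paired_ttest <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 2)
    stop("'pairs' must have two columns and at least two rows")
  d <- pairs[, 1] - pairs[, 2]
  if (all(d == 0)) return(list(t = 0, df = nrow(pairs) - 1, p = 1))
  if (sd(d) == 0)
    return(list(t = sign(d[1]) * Inf, df = nrow(pairs) - 1, p = 0,
                flag = "zero_variance"))
  ht <- t.test(pairs[, 1], pairs[, 2], paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
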