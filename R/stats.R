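## Cohort statistics: per-measure two-sample t-tests from group summaries
## and a-priori power analysis under the noncentral t distribution.

#' Group summary for one measure
#'
#' @param measure measure name.
#' @param n1,n2 group sizes (>= 2).
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group sample SDs (>= 0).
#' @return list of class "GroupSummary".
#' @export
groupSummary <- function(measure, n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  structure(list(measure = measure, n1 = as.integer(n1), mean1 = mean1,
                 sd1 = sd1, n2 = as.integer(n2), mean2 = mean2, sd2 = sd2),
            class = "GroupSummary")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student test by default:
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `t = (m1-m2) / (s_p sqrt(1/n1 + 1/n2))`, two-tailed p from the central
#' t at `df = n1+n2-2`. With `welch = TRUE`, the Welch unequal-variance
#' test (Welch-Satterthwaite df) is used instead.
#'
#' @param summary a [groupSummary()].
#' @param welch use the Welch test instead of the pooled Student test.
#' @return list of class "TTestResult": `t`, `df`, `p` (two-tailed),
#'   `mean_diff`.
#' @examples
#' twoSampleT(groupSummary("pelvic_depth", 100, 102.8, 9.8, 100, 111.5, 8.8))
#' @export
twoSampleT <- function(summary, welch = FALSE) {
  stopifnot(inherits(summary, "GroupSummary"))
  s <- summary
  diff <- s$mean1 - s$mean2
  if (s$sd1 == 0 && s$sd2 == 0) {
    if (diff == 0)
      return(structure(list(t = 0, df = s$n1 + s$n2 - 2L, p = 1,
                            mean_diff = 0), class = "TTestResult"))
    stop("both SDs are zero with unequal means: t is infinite")
  }
  if (welch) {
    v1 <- s$sd1^2 / s$n1; v2 <- s$sd2^2 / s$n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (s$n1 - 1) + v2^2 / (s$n2 - 1))
  } else {
    sp2 <- ((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) / (s$n1 + s$n2 - 2)
    se <- sqrt(sp2 * (1 / s$n1 + 1 / s$n2))
    df <- s$n1 + s$n2 - 2
  }
  tstat <- diff / se
  structure(list(t = tstat, df = df,
                 p = 2 * stats::pt(-abs(tstat), df), mean_diff = diff),
            class = "TTestResult")
}

#' A-priori power of the two-sample t-test
#'
#' For effect size `d` (standardized mean difference), group sizes `n1`,
#' `n2` and two-sided level `alpha`: noncentrality
#' `delta = d sqrt(n1 n2 / (n1 + n2))`, critical value the central-t
#' quantile at `1 - alpha/2` with `df = n1 + n2 - 2`, and power
#' `P(|T| > t_crit)` under the noncentral t with that noncentrality.
#'
#' @param d effect size (> 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided type-I error level in (0, 1).
#' @return list of class "PowerResult": `d`, `alpha`, `n1`, `n2`, `ncp`,
#'   `t_crit`, `df`, `power`.
#' @examples
#' tPower(d = 0.4, n1 = 100, n2 = 100, alpha = 0.05)
#' @export
tPower <- function(d, n1, n2, alpha = 0.05) {
  stopifnot_scalar(d, "d", positive = TRUE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  power <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  structure(list(d = d, alpha = alpha, n1 = as.integer(n1),
                 n2 = as.integer(n2), ncp = ncp, t_crit = tc, df = df,
                 power = power),
            class = "PowerResult")
}

#' @export
print.PowerResult <- function(x, ...) {
  cat(sprintf(paste0("Two-sample t-test a-priori power (two-tailed)\n",
                     "  d = %.4g, alpha = %.4g, n = %d/%d\n",
                     "  noncentrality = %.7f\n  critical t    = %.7f\n",
                     "  df            = %d\n  power         = %.7f\n"),
              x$d, x$alpha, x$n1, x$n2, x$ncp, x$t_crit, x$df, x$power))
  invisible(x)
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, two-tailed p = %.4g (mean diff %.4g)\n",
              x$t, x$df, x$p, x$mean_diff))
  invisible(x)
}

#' Sex-stratified cohort comparison over the 21-measure registry
#'
#' Summarizes two groups of pelvimetry records measure by measure (sample
#' means and n-1 SDs) and tests each group difference with [twoSampleT()].
#' No multiple-testing correction enters the per-measure p-values;
#' Bonferroni and Benjamini-Hochberg adjusted columns are appended as
#' supplementary output only.
#'
#' @param records list of [PelvimetryRecord-class] objects (or a numeric
#'   matrix with registry columns).
#' @param labels factor/character of group labels, one per record; exactly
#'   two levels, each with >= 2 records. The first level (alphabetical,
#'   or factor order) is group 1.
#' @param welch passed to [twoSampleT()].
#' @return data.frame with 21 rows in registry order: `measure`, `n1`,
#'   `mean1`, `sd1`, `n2`, `mean2`, `sd2`, `t`, `df`, `p`,
#'   `p_bonferroni`, `p_bh`.
#' @export
cohortTable <- function(records, labels, welch = FALSE) {
  if (is.list(records))
    records <- t(vapply(records, function(r) {
      stopifnot(is(r, "PelvimetryRecord")); r@measures
    }, numeric(21)))
  reg <- measureRegistry()
  stopifnot(identical(colnames(records), reg$measure))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two levels")
  if (length(labels) != nrow(records))
    stop("one label per record is required")
  g1 <- records[labels == levels(labels)[1], , drop = FALSE]
  g2 <- records[labels == levels(labels)[2], , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("each group needs at least 2 records")
  rows <- lapply(reg$measure, function(m) {
    gs <- groupSummary(m, nrow(g1), mean(g1[, m]), stats::sd(g1[, m]),
                       nrow(g2), mean(g2[, m]), stats::sd(g2[, m]))
    tt <- twoSampleT(gs, welch = welch)
    data.frame(measure = m, n1 = gs$n1, mean1 = gs$mean1, sd1 = gs$sd1,
               n2 = gs$n2, mean2 = gs$mean2, sd2 = gs$sd2,
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p, "bonferroni")
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}
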