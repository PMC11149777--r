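# Statistical core: branch-median aggregation, ordinary least squares of
# medians on divergence time (linear or log10 time), rate slopes and
# extrapolation, Wilcoxon between-class tests, per-amino-acid age
# correlations and 2x2 ratio statistics.

#' Median of a metric per branch, paired with divergence time
#'
#' @param values Named list: one numeric vector of per-protein values per
#'   branch (names are branch ids).
#' @param branch_table Branch-time table (see [default_branch_table()]).
#' @return A `data.frame` with columns `branch`, `time_mya`, `median`, `n`,
#'   ordered by time. Medians use the usual convention (even n: mean of
#'   the central pair).
#' @export
branch_medians <- function(values, branch_table = default_branch_table()) {
  if (length(values) == 0L) stop_ds("no branches supplied")
  if (any(!vapply(values, length, integer(1))))
    NULL
  empty <- names(values)[vapply(values, length, integer(1)) == 0L]
  if (length(empty))
    stop_ds("branch(es) with no values: %s", paste(empty, collapse = ", "))
  times <- branch_time(names(values), branch_table)
  out <- data.frame(
    branch = names(values), time_mya = times,
    median = vapply(values, stats::median, numeric(1)),
    n = vapply(values, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$time_mya), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_trend_fit <- function(fit, n, time_scale) {
  # exact lines (zero residual) make summary.lm warn; the coefficients are
  # still what we report
  s <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = unname(s$coefficients[2, 4]),
    adj_r2 = s$adj.r.squared,
    n_points = n, time_scale = time_scale),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> median = %.4g %s %.4g * %s  (n = %d, p = %.3g, adj R2 = %.3f)\n",
              x$intercept, if (x$slope < 0) "-" else "+", abs(x$slope),
              if (x$time_scale == "log10") "log10(t)" else "t",
              x$n_points, x$p_value, x$adj_r2))
  invisible(x)
}

#' Fit a linear trend of branch medians on divergence time
#'
#' Ordinary least squares of the median on time in Mya (the same model as
#' `lm(median ~ time)`): the slope is the rate of change of the metric per
#' million years; its two-sided t-test p-value and the adjusted R-squared
#' are returned.
#'
#' @param points A `data.frame` with columns `time_mya` and `median`
#'   (e.g. from [branch_medians()]), at least 3 rows, distinct times.
#' @return A `trend_fit` object with fields `slope`, `intercept`,
#'   `p_value`, `adj_r2`, `n_points`, `time_scale`.
#' @export
fit_linear_trend <- function(points) {
  if (nrow(points) < 3L) stop_ds("need at least 3 points for a trend fit")
  if (length(unique(points$time_mya)) < 2L) stop_ds("degenerate times")
  fit <- stats::lm(median ~ time_mya, data = points)
  new_trend_fit(fit, nrow(points), "linear")
}

#' Fit a trend of branch medians on log10 time
#'
#' As [fit_linear_trend()] but regressing on `log10(time)`; the slope is
#' per log10-My unit. All times must be strictly positive.
#'
#' @inheritParams fit_linear_trend
#' @return A `trend_fit` with `time_scale = "log10"`.
#' @export
fit_log10_trend <- function(points) {
  if (nrow(points) < 3L) stop_ds("need at least 3 points for a trend fit")
  if (any(points$time_mya <= 0))
    stop_ds("log10 time scale requires strictly positive times")
  pts <- data.frame(median = points$median,
                    log10_time = log10(points$time_mya))
  fit <- stats::lm(median ~ log10_time, data = pts)
  new_trend_fit(fit, nrow(points), "log10")
}

#' Time for a linear trend to reach a benchmark value
#'
#' Inverts a linear fit: `t = (benchmark - intercept) / slope`. Errors if
#' the slope is zero or the benchmark lies backwards in time under the
#' fitted direction of change.
#'
#' @param fit A `trend_fit` on the linear time scale.
#' @param benchmark Target metric value.
#' @return Time in My.
#' @examples
#' f <- fit_linear_trend(data.frame(time_mya = 0:3, median = 1 - 0.14 * 0:3))
#' time_to_benchmark(f, 0.31)
#' @export
time_to_benchmark <- function(fit, benchmark) {
  stopifnot(inherits(fit, "trend_fit"))
  if (fit$time_scale != "linear")
    stop_ds("extrapolation requires a linear-time fit")
  if (fit$slope == 0) stop_ds("zero slope: benchmark unreachable")
  t <- (benchmark - fit$intercept) / fit$slope
  if (t < 0)
    stop_ds("benchmark %.3g lies backwards in time under this fit", benchmark)
  t
}

#' Wilcoxon rank-sum test between two samples
#'
#' Exact null enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction (both via [stats::wilcox.test()]).
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (x relative
#'   to y).
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_ds("both samples must be nonempty")
  alt <- sub("two_sided", "two.sided", alternative)
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 12 && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE)$p.value)
}

#' Per-amino-acid correlation of composition medians with gene age
#'
#' For each amino acid, the Pearson correlation (and p-value) between its
#' branch-median fraction and branch divergence time; positive `r` means
#' the fraction grows with age. Amino acids with constant medians have no
#' defined correlation and are flagged.
#'
#' @param medians Named list (one element per amino acid) of `data.frame`s
#'   with columns `time_mya` and `median`, at least 3 branches each.
#' @return A `data.frame` with columns `aa`, `r`, `p`, `defined`.
#' @export
per_aa_age_correlation <- function(medians) {
  rows <- lapply(names(medians), function(aa) {
    d <- medians[[aa]]
    if (nrow(d) < 3L) stop_ds("amino acid %s: need >= 3 branches", aa)
    res <- pearson_with_p(d$time_mya, d$median)
    data.frame(aa = aa, r = res$r, p = res$p, defined = res$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk or odds ratio for a 2x2 comparison
#'
#' Compares success proportions `a/n1` vs `b/n2` between two groups.
#' `kind = "risk"` gives the risk ratio `(a/n1) / (b/n2)`;
#' `kind = "odds"` the sample odds ratio `(a/(n1-a)) / (b/(n2-b))`.
#' The 95% CI is Wald on the log scale and the p-value a two-sided z-test
#' of log(ratio) = 0. Zero cells error unless `correct = TRUE` adds the
#' Haldane continuity correction of 0.5 to every cell. A Fisher exact
#' p-value is available with `fisher = TRUE`.
#'
#' @param a,n1 Successes and total in group 1.
#' @param b,n2 Successes and total in group 2.
#' @param kind `"risk"` or `"odds"`.
#' @param correct Apply the 0.5 continuity correction (default `FALSE`).
#' @param fisher Replace the z-test p-value with Fisher's exact test.
#' @return A list with `estimate`, `ci_low`, `ci_high`, `p`, `kind`.
#' @examples
#' ratio_2x2(53, 215, 26, 252, kind = "risk")$estimate  # 2.389
#' ratio_2x2(53, 215, 26, 252, kind = "odds")$estimate  # 2.844
#' @export
ratio_2x2 <- function(a, n1, b, n2, kind = c("risk", "odds"),
                      correct = FALSE, fisher = FALSE) {
  kind <- match.arg(kind)
  if (a < 0 || b < 0 || a > n1 || b > n2)
    stop_ds("counts must satisfy 0 <= a <= n1 and 0 <= b <= n2")
  # only cells the estimator divides by can break it: a and b for the risk
  # ratio, all four cells for the odds ratio
  breaking <- if (kind == "risk") c(a, b) else c(a, n1 - a, b, n2 - b)
  if (any(breaking == 0)) {
    if (!correct)
      stop_ds("zero cell in the 2x2 table; set correct = TRUE")
    a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 1; n2 <- n2 + 1
  }
  if (kind == "risk") {
    est <- (a / n1) / (b / n2)
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  } else {
    est <- (a / (n1 - a)) / (b / (n2 - b))
    se <- sqrt(1 / a + 1 / (n1 - a) + 1 / b + 1 / (n2 - b))
  }
  z <- if (se == 0) 0 else log(est) / se
  p <- if (fisher) {
    m <- matrix(round(c(a, n1 - a, b, n2 - b)), nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  } else 2 * stats::pnorm(-abs(z))
  list(estimate = est,
       ci_low = exp(log(est) - 1.959964 * se),
       ci_high = exp(log(est) + 1.959964 * se),
       p = p, kind = kind)
}
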